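# Motor-domain (kinesin) analysis recipe: parameter set for the
# crystal-ensemble and trajectory pipelines.
core_stop_volume: 0.5      # A^3, invariant-core stop criterion
network_cutoff: 4.5        # A, heavy-atom contact cutoff
network_occupancy: 0.75    # fraction of frames a contact must persist
event_on: 6.5              # A, contact-on cutoff (hysteresis)
event_off: 7.5             # A, contact-off cutoff
half_width_ns: 14          # ns, median-filter half-width
time_step_ns: 0.02         # ns, snapshot spacing (20 ps)
k_clusters: 3              # conformer groups cut from the dendrogram
n_pcs: 5                   # PCs used for clustering distance
docking_cutoff: 8.0        # A, Cbeta-Cbeta neck-linker docking cutoff
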