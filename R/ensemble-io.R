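#' Read protein chains from a PDB file
#'
#' Parses a PDB file and returns one `chain_record` per selected protein
#' chain. Each record carries the full atom table, the Calpha subset used for
#' ensemble analysis, a one-letter sequence, per-residue B-factors and any
#' heteroatom (nucleotide, inhibitor, ion) records as ligand annotations.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties: first in file).
#'
#' @param path path to a PDB file.
#' @param chains character vector of chain identifiers to keep, or `NULL`
#'   (default) for all protein chains.
#' @param id identifier prefix for the records; defaults to the file name
#'   without extension.
#' @return list of `chain_record` objects. Chains without any Calpha atom are
#'   skipped with a warning.
#' @export
read_structure <- function(path, chains = NULL, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  at <- as_tibble(pdb$atom)
  prot <- dplyr::filter(at, .data$type == "ATOM")
  het <- dplyr::filter(at, .data$type == "HETATM")
  found <- unique(prot$chain)
  keep <- if (is.null(chains)) found else intersect(chains, found)
  if (length(keep) == 0L) stop("no matching protein chain in ", path)
  out <- list()
  for (ch in keep) {
    rec <- chain_record_from_atoms(
      dplyr::filter(prot, .data$chain == ch),
      dplyr::filter(het, .data$chain == ch | is.na(.data$chain)),
      source_id = paste0(id, "_", ch)
    )
    if (is.null(rec)) {
      warning("chain ", ch, " of ", id, " has no Calpha atoms; skipped")
      next
    }
    out[[rec$source_id]] <- rec
  }
  out
}

# Resolve altlocs and assemble a chain_record from bio3d atom rows.
chain_record_from_atoms <- function(atoms, het, source_id) {
  if (!nrow(atoms)) return(NULL)
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms <- atoms |>
    dplyr::group_by(.data$resno, .data$elety) |>
    dplyr::slice_max(.data$o, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$resno, .data$eleno)
  ca <- dplyr::filter(atoms, .data$elety == "CA")
  if (!nrow(ca)) return(NULL)
  if (is.unsorted(ca$resno, strictly = TRUE))
    stop("residue numbers not strictly increasing in ", source_id)
  # representative side-chain atom: CB, falling back to CA (glycine)
  cb <- atoms |>
    dplyr::filter(.data$elety %in% c("CA", "CB")) |>
    dplyr::group_by(.data$resno) |>
    dplyr::arrange(dplyr::desc(.data$elety), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$resno %in% ca$resno)
  structure(
    list(
      source_id = source_id,
      atoms = atoms,
      ca = dplyr::select(ca, "resno", "resid", "x", "y", "z", "b"),
      cb = dplyr::select(cb, "resno", "x", "y", "z"),
      sequence = paste(bio3d::aa321(ca$resid), collapse = ""),
      ligands = if (nrow(het)) {
        dplyr::distinct(het, .data$resid, .data$resno) |>
          dplyr::rename(ligand = "resid")
      } else tibble(ligand = character(), resno = integer())
    ),
    class = "chain_record"
  )
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain_record> %s: %d residues", x$source_id, nrow(x$ca)))
  if (nrow(x$ligands))
    cat("; ligands:", paste(unique(x$ligands$ligand), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Build residue equivalences across chains by multiple sequence alignment
#'
#' Aligns the Calpha-bearing sequences of two or more chains and returns the
#' column map used to place heterogeneous chains into a common coordinate
#' frame. Ensemble analyses use only the columns occupied in every chain,
#' mirroring the restriction of interconformer PCA to regions with
#' equivalent residues in all structures.
#'
#' Identical sequences short-circuit to an identity map; otherwise the
#' alignment is delegated to the `mafft` executable (BLOSUM-scored
#' progressive MSA).
#'
#' @param chains list of `chain_record` objects (at least two).
#' @return an `equivalence_map`: an integer matrix (alignment columns x
#'   chains) of residue indices with `NA` at gaps; attribute `all_occupied`
#'   flags columns present in every chain. Chains with < 30% pairwise
#'   identity to every other chain trigger a curation warning.
#' @export
build_equivalences <- function(chains) {
  if (length(chains) < 2L) stop("need at least 2 chains")
  seqs <- vapply(chains, function(x) x$sequence, "")
  ids <- vapply(chains, function(x) x$source_id, "")
  if (length(unique(seqs)) == 1L) {
    n <- nchar(seqs[[1]])
    ali <- matrix(rep(strsplit(seqs[[1]], "")[[1]], length(seqs)),
                  nrow = length(seqs), byrow = TRUE)
  } else {
    ali <- run_mafft(seqs, ids)
  }
  # column -> residue index per chain
  map <- apply(ali, 1L, function(row) {
    idx <- cumsum(row != "-")
    ifelse(row == "-", NA_integer_, idx)
  })
  colnames(map) <- ids
  pid <- pairwise_identity(ali)
  diag(pid) <- NA
  low <- which(apply(pid, 1L, function(r) all(r < 0.3, na.rm = TRUE)))
  if (length(low))
    warning("chains with <30% identity to all others (flag for curation): ",
            paste(ids[low], collapse = ", "))
  structure(map, class = "equivalence_map",
            all_occupied = rowSums(is.na(map)) == 0L)
}

run_mafft <- function(seqs, ids) {
  exe <- Sys.which("mafft")
  if (exe == "") stop("mafft executable not found on PATH; required for MSA")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", seq_along(seqs), "\n", seqs), fin)
  status <- system2(exe, c("--auto", "--quiet", "--anysymbol", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  aln <- bio3d::read.fasta(fout)$ali
  aln <- toupper(aln[order(as.integer(rownames(aln))), , drop = FALSE])
  aln
}

pairwise_identity <- function(ali) {
  n <- nrow(ali)
  pid <- diag(1, n)
  if (n < 2L) return(pid)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- ali[i, ] != "-" & ali[j, ] != "-"
    pid[i, j] <- pid[j, i] <-
      if (any(both)) mean(ali[i, both] == ali[j, both]) else 0
  }
  pid
}

#' @export
print.equivalence_map <- function(x, ...) {
  cat(sprintf("<equivalence_map> %d columns x %d chains; %d all-occupied\n",
              nrow(x), ncol(x), sum(attr(x, "all_occupied"))))
  invisible(x)
}

#' Columns occupied in every chain
#' @param map an `equivalence_map`.
#' @return integer vector of alignment column indices.
#' @export
occupied_columns <- function(map) which(attr(map, "all_occupied"))

#' Filter chains by completeness of required regions
#'
#' Applies the completeness filter used before interconformer analysis:
#' a chain is retained only if every alignment column of every required
#' region (by default, key nucleotide-binding-site elements such as the
#' P-loop and the two switch loops) maps to a resolved residue.
#'
#' @param chains list of `chain_record`s.
#' @param map `equivalence_map` over the same chains (same order).
#' @param required_regions named list of integer alignment-column vectors.
#' @return list with `retained` (chain list), `map` (columns of the retained
#'   chains), and `exclusions` — a tibble (source_id, missing_region) with one
#'   row per chain x missing region. Empty retained set is an error. The
#'   operation is idempotent and independent of chain order.
#' @export
filter_structures <- function(chains, map, required_regions) {
  stopifnot(length(chains) == ncol(map))
  if (!length(required_regions)) stop("required_regions must be non-empty")
  if (is.null(names(required_regions)))
    names(required_regions) <- paste0("region", seq_along(required_regions))
  excl <- purrr::imap(required_regions, function(cols, name) {
    bad <- which(colSums(is.na(map[cols, , drop = FALSE])) > 0L)
    if (!length(bad)) return(NULL)
    tibble(source_id = colnames(map)[bad], missing_region = name)
  }) |> purrr::compact() |> purrr::list_rbind()
  if (is.null(excl) || !nrow(excl))
    excl <- tibble(source_id = character(), missing_region = character())
  drop <- unique(excl$source_id)
  keep <- setdiff(colnames(map), drop)
  if (!length(keep)) stop("completeness filter excluded every chain")
  keep_idx <- match(keep, colnames(map))
  sub <- map[, keep_idx, drop = FALSE]
  list(
    retained = chains[keep_idx],
    map = structure(sub, class = "equivalence_map",
                    all_occupied = rowSums(is.na(sub)) == 0L),
    exclusions = dplyr::arrange(excl, .data$source_id, .data$missing_region)
  )
}

#' Write an exclusion report as TSV
#' @param exclusions tibble from [filter_structures()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_exclusion_report <- function(exclusions, path) {
  write.table(exclusions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a coordinate ensemble from equivalenced chains
#'
#' @param chains list of `chain_record`s.
#' @param map `equivalence_map` over those chains.
#' @param columns alignment columns to retain; default all-occupied columns.
#' @param reference index of the chain providing residue numbering and
#'   B-factors (default 1).
#' @return a [coord_ensemble()] with one frame per chain.
#' @export
ensemble_from_chains <- function(chains, map, columns = NULL, reference = 1L) {
  stopifnot(length(chains) == ncol(map))
  if (is.null(columns)) columns <- occupied_columns(map)
  if (any(colSums(is.na(map[columns, , drop = FALSE])) > 0L))
    stop("requested columns are not occupied in all chains")
  n <- length(columns)
  grab <- function(tbl, idx) as.vector(t(as.matrix(tbl[idx, c("x", "y", "z")])))
  xyz <- t(vapply(seq_along(chains), function(k)
    grab(chains[[k]]$ca, map[columns, k]), numeric(3L * n)))
  cb <- t(vapply(seq_along(chains), function(k)
    grab(chains[[k]]$cb, map[columns, k]), numeric(3L * n)))
  ref <- chains[[reference]]
  ridx <- map[columns, reference]
  coord_ensemble(
    xyz,
    labels = vapply(chains, function(x) x$source_id, ""),
    resno = ref$ca$resno[ridx], resid = ref$ca$resid[ridx],
    cb = cb, bfactors = ref$ca$b[ridx]
  )
}

#' Read a trajectory into a coordinate ensemble
#'
#' Multi-model PDB is always supported; DCD trajectories are read through
#' `bio3d::read.dcd` against a PDB topology. Calpha (and representative
#' side-chain) subsets are extracted from the topology.
#'
#' @param topology path to a PDB file defining atoms (for multi-model PDB
#'   input, the same file may serve as both topology and trajectory).
#' @param trajectory path to a multi-model PDB or DCD file; default the
#'   topology itself.
#' @param stride keep every `stride`-th frame (default 1).
#' @param time_step frame spacing in ns of the *input* frames (default 0.02,
#'   i.e. 20 ps snapshots); stored spacing is `time_step * stride`.
#' @return a [coord_ensemble()] with time labels in ns.
#' @export
read_trajectory <- function(topology, trajectory = topology, stride = 1L,
                            time_step = 0.02) {
  top <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
  is_dcd <- grepl("\\.dcd$", trajectory, ignore.case = TRUE)
  xyz_all <- if (is_dcd) {
    m <- bio3d::read.dcd(trajectory, verbose = FALSE)
    if (ncol(m) != ncol(top$xyz))
      stop(sprintf("atom-count mismatch: topology %d vs trajectory %d atoms",
                   ncol(top$xyz) %/% 3L, ncol(m) %/% 3L))
    m
  } else if (identical(trajectory, topology)) {
    top$xyz
  } else {
    tr <- bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE)
    if (ncol(tr$xyz) != ncol(top$xyz))
      stop(sprintf("atom-count mismatch: topology %d vs trajectory %d atoms",
                   ncol(top$xyz) %/% 3L, ncol(tr$xyz) %/% 3L))
    tr$xyz
  }
  if (is.null(dim(xyz_all))) xyz_all <- matrix(xyz_all, nrow = 1L)
  frames <- seq(1L, nrow(xyz_all), by = as.integer(stride))
  at <- top$atom
  ca_sel <- which(at$elety == "CA" & at$type == "ATOM")
  if (!length(ca_sel)) stop("topology has no Calpha atoms")
  resno <- at$resno[ca_sel]
  cb_sel <- vapply(seq_along(ca_sel), function(k) {
    hit <- which(at$resno == resno[k] & at$elety == "CB" & at$type == "ATOM")
    if (length(hit)) hit[1L] else ca_sel[k]
  }, integer(1))
  coord_ensemble(
    xyz_all[frames, xyz_idx(ca_sel), drop = FALSE],
    labels = (frames - 1L) * time_step,
    resno = resno, resid = at$resid[ca_sel],
    cb = xyz_all[frames, xyz_idx(cb_sel), drop = FALSE],
    time_step = time_step * as.integer(stride)
  )
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' Frames become MODEL/ENDMDL blocks of CA (and, when present, CB) ATOM
#' records. Coordinates round-trip through [read_trajectory()] at the PDB
#' fixed-format precision of 0.001 Angstrom.
#'
#' @param x a [coord_ensemble()].
#' @param path output file.
#' @param chain chain identifier to write (default `"A"`).
#' @return invisibly, `path`.
#' @export
write_ensemble_pdb <- function(x, path, chain = "A") {
  n <- n_positions(x)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  for (f in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    ca <- frame_coords(x, f)
    cb <- if (!is.null(x$cb)) frame_coords(x, f, "cb") else NULL
    serial <- 0L
    lines <- character(0)
    for (i in seq_len(n)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, " CA", x$resid[i], chain,
                                x$resno[i], ca[i, 1], ca[i, 2], ca[i, 3],
                                1, 0))
      if (!is.null(cb) && any(cb[i, ] != ca[i, ])) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(fmt, serial, " CB", x$resid[i], chain,
                                  x$resno[i], cb[i, 1], cb[i, 2], cb[i, 3],
                                  1, 0))
      }
    }
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
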