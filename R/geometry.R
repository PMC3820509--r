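#' Resolve a region selection to position indices
#'
#' Selections may be given as integer position vectors, as the name of an
#' entry of the ensemble's `regions` list, or as author residue numbers via
#' `resno = TRUE`.
#'
#' @param x a [coord_ensemble()].
#' @param sel integer positions, region name, or residue numbers.
#' @param resno interpret numeric `sel` as author residue numbers.
#' @return integer position indices.
#' @export
resolve_selection <- function(x, sel, resno = FALSE) {
  if (is.character(sel)) {
    if (is.null(x$regions) || is.null(x$regions[[sel]]))
      stop("unknown region: ", sel)
    return(x$regions[[sel]])
  }
  if (resno) {
    idx <- match(sel, x$resno)
    if (anyNA(idx)) stop("residue number(s) not present: ",
                         paste(sel[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(sel)
}

principal_axis <- function(coords) {
  c0 <- sweep(coords, 2L, colMeans(coords))
  eigen(crossprod(c0) / nrow(c0), symmetric = TRUE)$vectors[, 1L]
}

#' Subdomain protrusion distance and angle
#'
#' Per frame: the distance between the (mass-uniform Calpha) centers of mass
#' of two selections, and the angle between the selections' dominant
#' principal axes, folded to [0, 90] degrees. With the mobile helix (e.g.
#' alpha4) as one selection and a core strand (e.g. beta3) as the other,
#' this order parameter tracks protrusion of the subdomain from the core of
#' the fold: the "up" conformation shows larger distance/angle than "down".
#' Both measures are invariant under global rigid motion of a frame.
#'
#' @param x a [coord_ensemble()].
#' @param sel_a,sel_b selections (see [resolve_selection()]); each needs at
#'   least 3 residues for a defined axis.
#' @return tibble with `frame`, `label`, `distance` (Angstrom), `angle`
#'   (degrees).
#' @export
protrusion <- function(x, sel_a, sel_b) {
  a <- resolve_selection(x, sel_a)
  b <- resolve_selection(x, sel_b)
  if (length(a) < 3L || length(b) < 3L)
    stop("protrusion selections need at least 3 residues (axis undefined)")
  res <- vapply(seq_len(n_frames(x)), function(f) {
    m <- frame_coords(x, f)
    ca <- m[a, , drop = FALSE]; cb <- m[b, , drop = FALSE]
    d <- sqrt(sum((colMeans(ca) - colMeans(cb))^2))
    cosang <- abs(sum(principal_axis(ca) * principal_axis(cb)))
    c(d, acos(pmin(cosang, 1)) * 180 / pi)
  }, numeric(2))
  tibble(frame = seq_len(n_frames(x)), label = x$labels,
         distance = res[1L, ], angle = res[2L, ])
}

#' Neck-linker docking state trace
#'
#' Monitors a set of residue-pair distances (Cbeta-Cbeta by default, via the
#' ensemble's representative side-chain atoms) and calls a frame "docked"
#' iff every monitored distance is below the cutoff. Raising the cutoff can
#' therefore never convert a docked call to undocked.
#'
#' @param x a [coord_ensemble()] carrying side-chain coordinates.
#' @param pairs two-column matrix or data frame of residue positions (or
#'   author residue numbers with `resno = TRUE`).
#' @param cutoff docking cutoff in Angstrom (default 8).
#' @param resno interpret pair entries as author residue numbers.
#' @return a `docking_trace`: list with `trace` (tibble: frame, label, pair,
#'   i, j, distance), `calls` (tibble: frame, label, docked),
#'   `first_undocked` (frame index or `NA`), `cutoff`.
#' @export
docking_state <- function(x, pairs, cutoff = 8, resno = FALSE) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  pi_ <- resolve_selection(x, pairs[, 1L], resno = resno)
  pj <- resolve_selection(x, pairs[, 2L], resno = resno)
  f <- n_frames(x)
  d <- matrix(NA_real_, f, length(pi_))
  for (k in seq_len(f)) {
    cb <- frame_coords(x, k, "cb")
    d[k, ] <- sqrt(rowSums((cb[pi_, , drop = FALSE] -
                              cb[pj, , drop = FALSE])^2))
  }
  docked <- apply(d < cutoff, 1L, all)
  first_undocked <- if (any(!docked)) which(!docked)[1L] else NA_integer_
  trace <- tibble(
    frame = rep(seq_len(f), times = length(pi_)),
    label = rep(x$labels, times = length(pi_)),
    pair = rep(seq_along(pi_), each = f),
    i = rep(x$resno[pi_], each = f), j = rep(x$resno[pj], each = f),
    distance = as.vector(d))
  structure(list(trace = trace,
                 calls = tibble(frame = seq_len(f), label = x$labels,
                                docked = docked),
                 first_undocked = first_undocked, cutoff = cutoff),
            class = "docking_trace")
}

#' @export
print.docking_trace <- function(x, ...) {
  cat(sprintf("<docking_trace> %d frames, %d pairs, cutoff %.1f A; %s\n",
              nrow(x$calls), length(unique(x$trace$pair)), x$cutoff,
              if (is.na(x$first_undocked)) "docked throughout" else
                paste0("first undocked at frame ", x$first_undocked)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.docking_trace <- function(x, ...) {
  dplyr::left_join(x$trace, x$calls, by = c("frame", "label"))
}

#' Pairwise interaction distance traces between residue groups
#'
#' For every pair of the supplied residue groups (e.g. latch residues and
#' the inter-switch salt bridge partners), reports the per-frame minimum
#' representative-atom distance and the fraction of frames in contact at the
#' given cutoff.
#'
#' @param x a [coord_ensemble()].
#' @param groups named list of selections (see [resolve_selection()]).
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @param resno interpret numeric selections as author residue numbers.
#' @return list with `trace` (tibble: frame, label, pair, distance) and
#'   `summary` (tibble: pair, formed_fraction).
#' @export
interaction_trace <- function(x, groups, cutoff = 4.5, resno = FALSE) {
  sels <- lapply(groups, resolve_selection, x = x, resno = resno)
  nm <- names(sels)
  if (is.null(nm)) nm <- paste0("group", seq_along(sels))
  combos <- t(combn(seq_along(sels), 2L))
  f <- n_frames(x)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    a <- sels[[combos[r, 1L]]]; b <- sels[[combos[r, 2L]]]
    dmin <- vapply(seq_len(f), function(k) {
      dm <- residue_min_dist(x, k)
      min(dm[a, b])
    }, numeric(1))
    out[[r]] <- tibble(frame = seq_len(f), label = x$labels,
                       pair = paste(nm[combos[r, 1L]], nm[combos[r, 2L]],
                                    sep = "-"),
                       distance = dmin)
  }
  trace <- purrr::list_rbind(out)
  summary <- trace |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(formed_fraction = mean(.data$distance < cutoff),
                     .groups = "drop")
  list(trace = trace, summary = summary)
}

# Calpha-geometry secondary-structure assignment for one frame.
# Helix/strand calls use characteristic CA(i,i+2), CA(i,i+3), CA(i,i+4)
# distances (P-SEA-style criteria); ends and short segments fall to coil.
assign_ss_ca <- function(coords) {
  n <- nrow(coords)
  cls <- rep("coil", n)
  if (n < 5L) return(cls)
  dk <- function(k) {
    i <- seq_len(n - k)
    sqrt(rowSums((coords[i + k, , drop = FALSE] -
                    coords[i, , drop = FALSE])^2))
  }
  d2 <- dk(2L); d3 <- dk(3L); d4 <- dk(4L)
  for (i in seq_len(n - 4L)) {
    if (d3[i] > 4.5 && d3[i] < 6.0 && d4[i] > 5.0 && d4[i] < 7.2) {
      cls[i:(i + 4L)] <- "helix"
    }
  }
  for (i in seq_len(n - 3L)) {
    if (cls[i] == "coil" && d2[i] > 6.0 && d3[i] > 8.5) {
      take <- i:(i + 3L)
      cls[take][cls[take] == "coil"] <- "strand"
    }
  }
  cls
}

#' Secondary-structure content trace
#'
#' Assigns helix/strand/coil per residue per frame. The built-in backend
#' works from Calpha geometry alone (characteristic i,i+2 / i,i+3 / i,i+4
#' distances); an external assigner can be plugged in as a function taking
#' an N x 3 Calpha matrix and returning a character class vector, which also
#' lets a full-backbone assigner stand behind the same surface.
#'
#' @param x a [coord_ensemble()].
#' @param backend `NULL` for the built-in assigner, or a function.
#' @param regions optional named list of selections for per-region content
#'   summaries (defaults to the ensemble's `regions`).
#' @return list with `classes` (tibble: frame, label, position, resno,
#'   class) and `content` (tibble: frame, label, region, helix, strand,
#'   coil fractions; only when regions are available).
#' @export
secondary_structure_trace <- function(x, backend = NULL, regions = NULL) {
  if (is.null(backend)) backend <- assign_ss_ca
  if (is.null(regions)) regions <- x$regions
  f <- n_frames(x)
  n <- n_positions(x)
  cls <- vapply(seq_len(f), function(k) backend(frame_coords(x, k)),
                character(n))
  classes <- tibble(frame = rep(seq_len(f), each = n),
                    label = rep(x$labels, each = n),
                    position = rep(seq_len(n), times = f),
                    resno = rep(x$resno, times = f),
                    class = as.vector(cls))
  content <- NULL
  if (!is.null(regions)) {
    content <- purrr::imap(regions, function(sel, name) {
      sub <- cls[sel, , drop = FALSE]
      tibble(frame = seq_len(f), label = x$labels, region = name,
             helix = colMeans(sub == "helix"),
             strand = colMeans(sub == "strand"),
             coil = colMeans(sub == "coil"))
    }) |> purrr::list_rbind()
  }
  list(classes = classes, content = content)
}
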