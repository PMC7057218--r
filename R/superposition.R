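#' Optimal weighted rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (weighted)
#' r.m.s.d. between two paired coordinate sets, via SVD of the weighted
#' covariance matrix with the determinant sign fixed so that no reflection
#' is ever returned.
#'
#' @param coords_a n x 3 mobile coordinates
#' @param coords_b n x 3 reference coordinates
#' @param weights optional non-negative weights (length n)
#' @return list with `rotation` (3 x 3, det +1), `translation` (after
#'   rotation: `x %*% t(R) + t` maps a onto b), `rmsd` (weighted) and the
#'   per-pair residual `deviations`
#' @export
kabsch_rmsd <- function(coords_a, coords_b, weights = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  n <- nrow(coords_a)
  stopifnot(nrow(coords_b) == n, ncol(coords_a) == 3, ncol(coords_b) == 3)
  if (n < 3) stop("degenerate superposition: fewer than 3 atom pairs")
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  ca <- colSums(coords_a * w)
  cb <- colSums(coords_b * w)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  if (min(sv$d) < 1e-12 && sv$d[2] < 1e-12) {
    stop("degenerate superposition: collinear coordinate set")
  }
  moved <- A %*% t(R)
  dev <- sqrt(rowSums((moved - B)^2))
  rmsd <- sqrt(sum(w * dev^2))
  t_vec <- cb - as.vector(R %*% ca)
  list(rotation = R, translation = t_vec, rmsd = rmsd, deviations = dev)
}

#' Iterative inverse-variance weighted superposition
#'
#' Alternates optimal superposition with re-weighting of every atom pair to
#' the inverse of its variance about the fitted position (plus a small
#' epsilon to keep perfect pairs finite), normalized to mean 1. Outliers
#' are progressively downweighted, sharpening the fit of the consistent
#' core. Stops when the weighted r.m.s.d. changes by less than `tol` or
#' after `max_iter` iterations.
#'
#' @param coords_a,coords_b paired coordinate sets (n x 3)
#' @param eps variance floor in A^2
#' @param tol convergence tolerance on the r.m.s.d., Angstrom
#' @param max_iter iteration cap
#' @return as [kabsch_rmsd()], plus `weights` and `iterations`
#' @export
weighted_refine <- function(coords_a, coords_b, eps = 1e-4, tol = 1e-6,
                            max_iter = 20L) {
  n <- nrow(coords_a)
  w <- rep(1, n)
  fit <- kabsch_rmsd(coords_a, coords_b, w)
  last <- fit$rmsd
  iterations <- 1L
  for (i in seq_len(max_iter)) {
    w <- 1 / (fit$deviations^2 + eps)
    w <- w * n / sum(w)
    fit <- kabsch_rmsd(coords_a, coords_b, w)
    iterations <- iterations + 1L
    if (abs(fit$rmsd - last) < tol) break
    last <- fit$rmsd
  }
  fit$weights <- w
  fit$iterations <- iterations
  fit
}

# All (n_cut, c_cut) trim pairs for a fragment of given length: up to 3
# residues per extremity, only for fragments longer than 5 residues, and
# never trimming below 5 remaining residues.
trim_options <- function(len) {
  if (len <= 5) return(list(c(0L, 0L)))
  opts <- list()
  for (a in 0:3) for (b in 0:3) {
    if (a + b <= len - 5L) opts[[length(opts) + 1L]] <- c(a, b)
  }
  opts
}

# Backbone coordinate block (stacked N, CA, C, O or CA only) for residues
# start..end of a stretch.
residue_coords <- function(stretch, start, end, atoms = c("CA")) {
  do.call(rbind, lapply(atoms, function(a) {
    stretch$xyz[[a]][start:end, , drop = FALSE]
  }))
}

#' Superpose a small fold onto a target structure
#'
#' Correspondences come from the fold search: every geometric occurrence of
#' the template fold in the target is a candidate site. At each site all
#' extremity-trim combinations (up to three residues per end of every
#' fragment longer than five residues) are enumerated; each trimmed core is
#' refined with inverse-variance weighting and the lowest-r.m.s.d.
#' combination wins. Sites sharing target residues are reduced to the
#' better (lower r.m.s.d.) one; surviving sites are reported separately in
#' order of their position along the target.
#'
#' @param template a `cv_structure` (or path) defining the fold
#' @param target a `cv_structure` (or path) to search
#' @param ss_threshold,tt_threshold fold-search thresholds, percent
#' @param strictness_ah,strictness_bs annotation strictness for both models
#' @param atoms atom set for the final refinement (`c("N","CA","C","O")` or
#'   `"CA"`)
#' @param max_trim_combinations guard: fall back to greedy per-fragment
#'   trimming above this enumeration size
#' @return list of `cv_superposition` results, each with `rotation`,
#'   `translation`, `rmsd`, `core` (residue correspondence), `trimmed`,
#'   `site_index`, `weights`
#' @export
superpose_fold <- function(template, target, ss_threshold = 45,
                           tt_threshold = 55, strictness_ah = 0.5,
                           strictness_bs = 0.3, atoms = c("N", "CA", "C", "O"),
                           max_trim_combinations = 1e5) {
  if (is.character(template)) template <- parse_structure(template)
  if (is.character(target)) target <- parse_structure(target)
  ann_t <- annotate_structure(template, strictness_ah, strictness_bs)
  ann_g <- annotate_structure(target, strictness_ah, strictness_bs)
  if (length(ann_t$fragments) == 0) {
    stop("unusable template: no secondary-structure fragment annotated")
  }
  fm_t <- build_fold_matrix(ann_t)
  fm_g <- build_fold_matrix(ann_g)
  matches <- find_fold_occurrences(fm_t, fm_g, ss_threshold, tt_threshold)
  if (length(matches) == 0) return(list())

  results <- lapply(matches, function(m) {
    refine_site(ann_t, ann_g, m, atoms, max_trim_combinations)
  })
  # suppress overlapping sites: lower rmsd wins, ties -> earlier range
  first_res <- vapply(results, function(r) min(r$core$target_row), numeric(1))
  rms <- vapply(results, function(r) r$rmsd, numeric(1))
  ord <- order(rms, first_res)
  keep <- logical(length(results))
  used <- character(0)
  for (i in ord) {
    rr <- results[[i]]
    ids <- paste(rr$core$target_stretch, rr$core$target_row)
    if (!any(ids %in% used)) {
      keep[i] <- TRUE
      used <- c(used, ids)
    }
  }
  results <- results[keep]
  first_res <- first_res[keep]
  results <- results[order(first_res)]
  for (i in seq_along(results)) results[[i]]$site_index <- i
  results
}

# Refine one fold match: enumerate trims, weighted refinement, best core.
refine_site <- function(ann_t, ann_g, match, atoms, max_combo) {
  nf <- nrow(match$assignment)
  opts <- lapply(seq_len(nf), function(i) {
    trim_options(match$assignment$length[i])
  })
  n_combo <- prod(vapply(opts, length, 1L))
  combos <- if (n_combo <= max_combo) {
    expand_trim_grid(opts)
  } else {
    greedy_trims(ann_t, ann_g, match, opts, atoms)
  }
  best <- NULL
  best_key <- NULL
  for (cb in combos) {
    pc <- site_pairing(ann_t, ann_g, match, cb, atoms)
    if (nrow(pc$a) < 3) next
    fit <- weighted_refine(pc$a, pc$b)
    key <- c(fit$rmsd, sum(unlist(cb)))
    if (is.null(best) || key[1] < best_key[1] - 1e-12 ||
        (abs(key[1] - best_key[1]) <= 1e-12 && key[2] < best_key[2])) {
      best <- list(fit = fit, trims = cb, core = pc$core)
      best_key <- key
    }
  }
  structure(list(rotation = best$fit$rotation,
                 translation = best$fit$translation,
                 rmsd = best$fit$rmsd, weights = best$fit$weights,
                 core = best$core, trimmed = best$trims,
                 match = match, site_index = NA_integer_),
            class = "cv_superposition")
}

expand_trim_grid <- function(opts) {
  grid <- list(list())
  for (o in opts) {
    grid <- unlist(lapply(grid, function(g) {
      lapply(o, function(x) c(g, list(x)))
    }), recursive = FALSE)
  }
  grid
}

# Greedy fallback: optimize each fragment's trim in turn, others fixed at 0.
greedy_trims <- function(ann_t, ann_g, match, opts, atoms) {
  nf <- length(opts)
  current <- lapply(seq_len(nf), function(i) c(0L, 0L))
  for (i in seq_len(nf)) {
    best_r <- Inf; best_o <- c(0L, 0L)
    for (o in opts[[i]]) {
      cb <- current; cb[[i]] <- o
      pc <- site_pairing(ann_t, ann_g, match, cb, atoms)
      if (nrow(pc$a) < 3) next
      r <- weighted_refine(pc$a, pc$b)$rmsd
      if (r < best_r) { best_r <- r; best_o <- o }
    }
    current[[i]] <- best_o
  }
  list(current)
}

# Paired coordinates (target = mobile a, template = reference b) for one
# match under a trim combination, plus the core correspondence table.
site_pairing <- function(ann_t, ann_g, match, trims, atoms) {
  a <- b <- matrix(numeric(0), 0, 3)
  core <- NULL
  for (i in seq_len(nrow(match$assignment))) {
    as_row <- match$assignment[i, ]
    cut <- trims[[i]]
    ts <- as_row$template_start + cut[1]
    te <- as_row$template_end - cut[2]
    gs <- as_row$target_start + cut[1]
    ge <- as_row$target_end - cut[2]
    if (te < ts) next
    st_t <- ann_t$structure$stretches[[as_row$template_stretch]]
    st_g <- ann_g$structure$stretches[[as_row$target_stretch]]
    b <- rbind(b, residue_coords(st_t, ts, te, atoms))
    a <- rbind(a, residue_coords(st_g, gs, ge, atoms))
    core <- rbind(core, data.frame(fragment = i,
                                   template_stretch = as_row$template_stretch,
                                   template_row = ts:te,
                                   target_stretch = as_row$target_stretch,
                                   target_row = gs:ge))
  }
  list(a = a, b = b, core = core)
}

#' @export
print.cv_superposition <- function(x, ...) {
  cat(sprintf("<cv_superposition> site %s: rmsd %.3f A over %d residues\n",
              x$site_index, x$rmsd, nrow(x$core)))
  invisible(x)
}

#' Write the target structure superposed onto the template frame
#'
#' Applies the site's rigid transform (which maps the matched target core
#' onto the template) to the whole target structure and writes it out.
#'
#' @param target the target `cv_structure`
#' @param result a `cv_superposition`
#' @param path output PDB file
#' @export
write_superposed <- function(target, result, path) {
  moved <- transform_structure(target, result$rotation, result$translation)
  write_structure(moved, path)
}
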