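#' Scoring parameters for secondary-structure annotation
#'
#' Each CV is scored against an ideal alpha-helix and an ideal beta-strand
#' with a penalty that combines three geometric descriptors: (a) the CV
#' modulus, (b) the mean angle to the CVs adjacent in sequence and (c) the
#' CA(i)--CA(i+2) span across the window. Each descriptor contributes
#' `w * min(1, |observed - ideal| / scale)`, so both scores live in [0, 1]
#' and the absolute score difference is directly comparable to the
#' strictness threshold. Ideals follow the CV statistics of canonical
#' elements (moduli 2.2 / 1.4 A; consecutive angles 7.5 / 52.5 degrees;
#' CA(i)--CA(i+2) spans 5.5 / 6.6 A); scales are set so that each ideal
#' geometry saturates the penalty of the opposite hypothesis.
#'
#' @param ideal_ah,ideal_bs named vectors (modulus, angle, ca_span)
#' @param scale scale constants per descriptor
#' @param weights descriptor weights (sum 1)
#' @param context_bonus fractional score bonus/penalty fed back from the
#'   labels of sequence-neighbour CVs during refinement iterations
#' @export
scoring_params <- function(ideal_ah = c(modulus = 2.2, angle = 7.5, ca_span = 5.5),
                           ideal_bs = c(modulus = 1.4, angle = 52.5, ca_span = 6.6),
                           scale = c(modulus = 0.8, angle = 45, ca_span = 1.1),
                           weights = c(modulus = 0.5, angle = 0.35, ca_span = 0.15),
                           context_bonus = 0.1) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  list(ideal_ah = ideal_ah, ideal_bs = ideal_bs, scale = scale,
       weights = weights, context_bonus = context_bonus)
}

# Descriptor table for every CV of a graph: modulus, mean neighbour angle
# (NA when the CV has no sequence neighbour), CA(i)-CA(i+2) span.
cv_descriptors <- function(graph, structure) {
  cvs <- graph$cvs
  k <- length(cvs$modulus)
  ang <- rep(NA_real_, k)
  span <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    nb <- which(cvs$stretch == cvs$stretch[i] &
                  abs(cvs$start - cvs$start[i]) == 1L)
    a <- graph$angle[i, nb]
    a <- a[!is.na(a)]
    if (length(a)) ang[i] <- mean(a)
    st <- structure$stretches[[cvs$stretch[i]]]
    r <- cvs$start[i]
    w <- cvs$window
    sp <- rowdist(st$xyz$CA[r:(r + w - 3L), , drop = FALSE],
                  st$xyz$CA[(r + 2L):(r + w - 1L), , drop = FALSE])
    span[i] <- mean(sp)
  }
  data.frame(modulus = cvs$modulus, angle = ang, ca_span = span)
}

penalty <- function(desc, ideal, params) {
  terms <- cbind(
    modulus = pmin(1, abs(desc$modulus - ideal["modulus"]) / params$scale["modulus"]),
    angle = pmin(1, abs(desc$angle - ideal["angle"]) / params$scale["angle"]),
    ca_span = pmin(1, abs(desc$ca_span - ideal["ca_span"]) / params$scale["ca_span"])
  )
  w <- matrix(params$weights, nrow(terms), 3, byrow = TRUE)
  # a CV without sequence neighbours has no angle descriptor: renormalize
  miss <- is.na(terms)
  w[miss] <- 0
  terms[miss] <- 0
  rowSums(terms * w) / rowSums(w)
}

#' Score and label every CV of a graph
#'
#' Base penalties against the helix and strand ideals are refined over a
#' few iterations in which the current labels of the sequence-neighbour CVs
#' grant a bonus (or penalty) of `context_bonus` times the score, improving
#' the reading of the structural environment; iteration stops at a label
#' fixed point (cap `max_iter`). The final label is the hypothesis with the
#' lowest adjusted score provided the absolute score difference exceeds
#' that hypothesis's strictness; otherwise the CV is coil. `max_strictness`
#' records the largest strictness at which the CV would keep a non-coil
#' label (the absolute score difference, clipped to [0, 1]).
#'
#' @param graph a `cv_graph`
#' @param structure the `cv_structure` the graph was computed from
#' @param strictness_ah,strictness_bs per-hypothesis thresholds in [0, 1]
#' @param params [scoring_params()]
#' @param max_iter refinement cap
#' @return data.frame with `score_ah`, `score_bs` (adjusted), `label`,
#'   `max_strictness` and `degenerate` per CV
#' @export
annotate_cvs <- function(graph, structure, strictness_ah = 0.5,
                         strictness_bs = 0.3, params = scoring_params(),
                         max_iter = 10L) {
  stopifnot(strictness_ah >= 0, strictness_ah <= 1,
            strictness_bs >= 0, strictness_bs <= 1)
  cvs <- graph$cvs
  k <- length(cvs$modulus)
  desc <- cv_descriptors(graph, structure)
  base_ah <- penalty(desc, params$ideal_ah, params)
  base_bs <- penalty(desc, params$ideal_bs, params)
  base_ah[cvs$degenerate] <- 1
  base_bs[cvs$degenerate] <- 1

  # context refinement, independent of strictness: argmin labels feed back
  argmin_label <- function(sa, sb) {
    lab <- ifelse(sa < sb, "ah", ifelse(sb < sa, "bs", "coil"))
    lab[cvs$degenerate] <- "coil"
    lab
  }
  adj_ah <- base_ah
  adj_bs <- base_bs
  lab <- argmin_label(adj_ah, adj_bs)
  cb <- params$context_bonus
  for (it in seq_len(max_iter)) {
    n_ah <- n_bs <- integer(k)
    for (i in seq_len(k)) {
      nb <- which(cvs$stretch == cvs$stretch[i] &
                    abs(cvs$start - cvs$start[i]) == 1L)
      n_ah[i] <- sum(lab[nb] == "ah")
      n_bs[i] <- sum(lab[nb] == "bs")
    }
    adj_ah <- pmin(1, pmax(0, base_ah * (1 - cb * n_ah + cb * n_bs)))
    adj_bs <- pmin(1, pmax(0, base_bs * (1 - cb * n_bs + cb * n_ah)))
    adj_ah[cvs$degenerate] <- 1
    adj_bs[cvs$degenerate] <- 1
    new_lab <- argmin_label(adj_ah, adj_bs)
    if (identical(new_lab, lab)) { lab <- new_lab; break }
    lab <- new_lab
  }

  diff <- pmin(1, abs(adj_ah - adj_bs))
  strict <- ifelse(lab == "ah", strictness_ah,
                   ifelse(lab == "bs", strictness_bs, 1))
  final <- ifelse(lab != "coil" & diff > strict, lab, "coil")
  data.frame(score_ah = adj_ah, score_bs = adj_bs, label = final,
             max_strictness = diff, degenerate = cvs$degenerate,
             stringsAsFactors = FALSE)
}

# Member CVs of residue r in stretch s (indices into the pooled cv_set).
residue_cv_members <- function(cvs, s, r) {
  which(cvs$stretch == s & cvs$start <= r & cvs$start + cvs$window - 1L >= r)
}

#' Translate CV labels into per-residue labels
#'
#' Three rules, applied in order: (i) a residue all of whose CVs carry one
#' non-coil label takes that label; (ii) a residue with two helix CVs, no
#' strand CV and a helix-labelled following residue becomes helix;
#' (iii) a coil residue with two strand CVs and no helix CV becomes strand,
#' as does a coil residue with at least one strand CV, no helix CV and a
#' coil residue among its two sequence neighbours on either side. The last
#' two rules recover terminal residues of fragments separated by short coil
#' spans. Residues participating in no CV are coil.
#'
#' @param cv_scores output of [annotate_cvs()]
#' @param cvs the pooled `cv_set`
#' @param structure the `cv_structure`
#' @return list of per-residue label vectors, one per stretch
#' @export
annotate_residues <- function(cv_scores, cvs, structure) {
  lab_cv <- cv_scores$label
  out <- vector("list", length(structure$stretches))
  for (s in seq_along(structure$stretches)) {
    n <- length(structure$stretches[[s]]$resno)
    members <- lapply(seq_len(n), function(r) residue_cv_members(cvs, s, r))
    cnt <- function(r, what) sum(lab_cv[members[[r]]] == what)
    lab <- rep("coil", n)
    # rule (i)
    for (r in seq_len(n)) {
      m <- members[[r]]
      if (length(m) && all(lab_cv[m] == "ah")) lab[r] <- "ah"
      else if (length(m) && all(lab_cv[m] == "bs")) lab[r] <- "bs"
    }
    # rule (ii): C- to N-terminal so extensions propagate
    if (n > 1) for (r in (n - 1):1) {
      if (lab[r] == "coil" && cnt(r, "ah") >= 2 && cnt(r, "bs") == 0 &&
          lab[r + 1] == "ah") lab[r] <- "ah"
    }
    # rule (iii)
    lab0 <- lab
    for (r in seq_len(n)) {
      if (lab0[r] != "coil" || cnt(r, "ah") > 0) next
      nb <- intersect(c(r - 2, r - 1, r + 1, r + 2), seq_len(n))
      if (cnt(r, "bs") >= 2 ||
          (cnt(r, "bs") >= 1 && any(lab0[nb] == "coil"))) lab[r] <- "bs"
    }
    out[[s]] <- lab
  }
  out
}

#' Group labelled residues into secondary-structure fragments
#'
#' Maximal runs of one non-coil label with at least three residues become
#' fragments; shorter runs are relabelled coil.
#'
#' @param residue_labels list of per-stretch label vectors
#' @param cvs the pooled `cv_set`
#' @param min_length minimum fragment length in residues
#' @return list with `fragments` (each: stretch, start, end, label, cv_idx =
#'   CVs whose window lies inside the run) and `labels` (the cleaned
#'   per-residue labels)
#' @export
group_fragments <- function(residue_labels, cvs, min_length = 3L) {
  fragments <- list()
  for (s in seq_along(residue_labels)) {
    lab <- residue_labels[[s]]
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] == "coil") next
      if (r$lengths[i] < min_length) {
        residue_labels[[s]][starts[i]:ends[i]] <- "coil"
        next
      }
      cv_idx <- which(cvs$stretch == s & cvs$start >= starts[i] &
                        cvs$start + cvs$window - 1L <= ends[i])
      fragments[[length(fragments) + 1L]] <- list(
        stretch = s, start = starts[i], end = ends[i],
        label = r$values[i], cv_idx = cv_idx)
    }
  }
  list(fragments = fragments, labels = residue_labels)
}

#' Pack beta-strands into sheets
#'
#' Two strands belong to the same sheet when at least `min_fraction` of the
#' CV--CV angles between the two fragments fall inside the parallel band or
#' inside the antiparallel band, and the minimum CV--CV distance between
#' the fragments is below `max_dist`. Sheets are the connected components
#' of this pairing relation (transitively closed); unpaired strands form
#' singleton sheets.
#'
#' @param fragments fragment list from [group_fragments()]
#' @param graph the `cv_graph`
#' @param min_fraction fraction of inter-fragment angles required in-band
#' @param max_dist distance bound, Angstrom
#' @param parallel_band,antiparallel_band angle bands, degrees.
#'   Tripeptide CVs tilt about 30 degrees off the strand axis, so angles
#'   between CVs of paired strands concentrate in [0, 40] (parallel) and
#'   [120, 180] (antiparallel); the defaults cover those empirical bands.
#' @return integer sheet id per fragment (NA for non-strands)
#' @export
detect_sheets <- function(fragments, graph, min_fraction = 0.4, max_dist = 6,
                          parallel_band = c(0, 40),
                          antiparallel_band = c(120, 180)) {
  nf <- length(fragments)
  sheet <- rep(NA_integer_, nf)
  bs <- which(vapply(fragments, function(f) f$label == "bs", TRUE))
  if (length(bs) == 0) return(sheet)
  k <- length(bs)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) for (a in 1:(k - 1)) for (b in (a + 1):k) {
    ia <- fragments[[bs[a]]]$cv_idx
    ib <- fragments[[bs[b]]]$cv_idx
    ang <- graph$angle[ia, ib, drop = FALSE]
    ang <- ang[!is.na(ang)]
    if (length(ang) == 0) next
    fr_par <- mean(ang >= parallel_band[1] & ang <= parallel_band[2])
    fr_anti <- mean(ang >= antiparallel_band[1] & ang <= antiparallel_band[2])
    dmin <- min(graph$dist[ia, ib])
    if ((fr_par >= min_fraction || fr_anti >= min_fraction) && dmin < max_dist) {
      parent[find(b)] <- find(a)
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  sheet[bs] <- match(roots, unique(roots))
  sheet
}

#' Build the fragment (supernode) graph
#'
#' Every secondary-structure fragment becomes a supernode gathering its
#' CVs; each pair of supernodes is connected by an edge annotated with the
#' minimum, maximum and mean of all inter-fragment CV angles and distances.
#' Edge weights are the inverse of the mean distance, multiplied by
#' `same_type_factor` when both fragments share a secondary-structure type,
#' which promotes the packing of beta-sheets during decomposition.
#'
#' @param fragments fragment list
#' @param graph the `cv_graph`
#' @param same_type_factor weight multiplier for same-type pairs
#' @return a `fragment_graph`: matrices `min_angle`, `max_angle`,
#'   `mean_angle`, `min_dist`, `max_dist`, `mean_dist`, `weight`, plus the
#'   fragment labels
#' @export
build_fragment_graph <- function(fragments, graph, same_type_factor = 2) {
  nf <- length(fragments)
  z <- matrix(0, nf, nf)
  out <- list(min_angle = z, max_angle = z, mean_angle = z,
              min_dist = z, max_dist = z, mean_dist = z, weight = z)
  if (nf > 1) for (a in 1:(nf - 1)) for (b in (a + 1):nf) {
    ia <- fragments[[a]]$cv_idx
    ib <- fragments[[b]]$cv_idx
    ang <- graph$angle[ia, ib, drop = FALSE]
    ang <- ang[!is.na(ang)]
    d <- graph$dist[ia, ib, drop = FALSE]
    set <- function(nm, v) out[[nm]][a, b] <<- out[[nm]][b, a] <<- v
    set("min_angle", if (length(ang)) min(ang) else NA_real_)
    set("max_angle", if (length(ang)) max(ang) else NA_real_)
    set("mean_angle", if (length(ang)) mean(ang) else NA_real_)
    set("min_dist", min(d))
    set("max_dist", max(d))
    set("mean_dist", mean(d))
    w <- 1 / mean(d)
    if (fragments[[a]]$label == fragments[[b]]$label) w <- w * same_type_factor
    set("weight", w)
  }
  out$fragments_label <- vapply(fragments, function(f) f$label, "")
  out$fragments <- fragments
  class(out) <- "fragment_graph"
  out
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat(sprintf("<fragment_graph> %d fragments (%s)\n",
              length(x$fragments_label), paste(x$fragments_label, collapse = " ")))
  invisible(x)
}

#' Full annotation of a structure
#'
#' Runs the whole pipeline: CV computation, complete CV graph, CV scoring
#' and labelling, residue rules, fragment grouping, sheet packing and the
#' fragment supernode graph.
#'
#' @param structure a `cv_structure`
#' @param strictness_ah,strictness_bs strictness thresholds in [0, 1]
#' @param window CV window size
#' @param params [scoring_params()]
#' @param same_type_factor see [build_fragment_graph()]
#' @return a `cv_annotation` object
#' @export
annotate_structure <- function(structure, strictness_ah = 0.5,
                               strictness_bs = 0.3, window = 3L,
                               params = scoring_params(),
                               same_type_factor = 2) {
  cvs <- structure_cvs(structure, window = window)
  if (length(cvs$modulus) == 0) {
    return(structure(list(structure = structure, cvs = cvs, graph = NULL,
                          cv_scores = NULL,
                          labels = lapply(structure$stretches,
                                          function(s) rep("coil", length(s$resno))),
                          fragments = list(), sheets = integer(0),
                          fragment_graph = NULL,
                          strictness = c(ah = strictness_ah, bs = strictness_bs)),
                     class = "cv_annotation"))
  }
  graph <- build_cv_graph(cvs)
  cv_scores <- annotate_cvs(graph, structure, strictness_ah, strictness_bs,
                            params = params)
  res_lab <- annotate_residues(cv_scores, cvs, structure)
  grp <- group_fragments(res_lab, cvs)
  sheets <- detect_sheets(grp$fragments, graph)
  fg <- if (length(grp$fragments) > 0) {
    build_fragment_graph(grp$fragments, graph, same_type_factor = same_type_factor)
  }
  structure(list(structure = structure, cvs = cvs, graph = graph,
                 cv_scores = cv_scores, labels = grp$labels,
                 fragments = grp$fragments, sheets = sheets,
                 fragment_graph = fg,
                 strictness = c(ah = strictness_ah, bs = strictness_bs)),
            class = "cv_annotation")
}

#' @export
print.cv_annotation <- function(x, ...) {
  p <- residue_percentages(x)
  cat(sprintf("<cv_annotation> %d CVs, %d fragments; %.0f%% helix, %.0f%% strand\n",
              length(x$cvs$modulus), length(x$fragments), p["ah"], p["bs"]))
  invisible(x)
}

#' Percentage of residues annotated helix / strand
#'
#' @param annotation a `cv_annotation`
#' @return named vector (`ah`, `bs`, `coil`), percentages over all residues
#' @export
residue_percentages <- function(annotation) {
  lab <- unlist(annotation$labels)
  c(ah = 100 * mean(lab == "ah"), bs = 100 * mean(lab == "bs"),
    coil = 100 * mean(lab == "coil"))
}

#' Per-residue maximum strictness
#'
#' For each residue, the largest strictness threshold at which it would
#' still be annotated as part of a secondary-structure element, aggregated
#' over its member CVs as the maximum of their score differences.
#'
#' @param annotation a `cv_annotation`
#' @return list of numeric vectors in [0, 1], one per stretch
#' @export
per_residue_strictness <- function(annotation) {
  cvs <- annotation$cvs
  ms <- annotation$cv_scores$max_strictness
  lapply(seq_along(annotation$structure$stretches), function(s) {
    n <- length(annotation$structure$stretches[[s]]$resno)
    vapply(seq_len(n), function(r) {
      m <- residue_cv_members(cvs, s, r)
      if (length(m) == 0) 0 else max(ms[m])
    }, numeric(1))
  })
}

#' Write the per-residue strictness map as a PDB file
#'
#' The per-residue maximum strictness, scaled to [0, 100], is written into
#' the B-factor column so the confidence of the annotation can be inspected
#' by colouring the model; low values flag ambiguous (coil-like or
#' distorted) geometry.
#'
#' @param annotation a `cv_annotation`
#' @param path output PDB path (conventionally `strictnesses.pdb`)
#' @return `path`, invisibly
#' @export
write_strictness_pdb <- function(annotation, path) {
  strc <- annotation$structure
  vals <- per_residue_strictness(annotation)
  for (s in seq_along(strc$stretches)) {
    strc$stretches[[s]]$b <- matrix(rep(100 * vals[[s]], 4),
                                    ncol = 4)
  }
  write_structure(strc, path)
}
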