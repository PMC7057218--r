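#' Fold matrix of an annotated structure
#'
#' The searchable representation of a fold: a square matrix over the CVs of
#' the structure's secondary-structure fragments, ordered along the chain.
#' The first diagonal stores each CV's modulus and label, the second
#' diagonal the (angle, distance) relation between contiguous CVs -- enough
#' to identify secondary-structure elements in linear time -- and the
#' off-diagonal cells the (angle, distance) relations characterizing the
#' fold (relations between CVs of different fragments).
#'
#' @param annotation a `cv_annotation` with at least one fragment
#' @return a `fold_matrix`: `moduli`, `labels`, `angle`, `dist` (square over
#'   all CVs of the structure, chain order), `frag` (fragment index per CV,
#'   NA outside fragments) and a `fragments` table (stretch, residue range,
#'   label, CV count)
#' @export
build_fold_matrix <- function(annotation) {
  frags <- annotation$fragments
  if (length(frags) == 0) stop("unusable template: no annotated fragments")
  cvs <- annotation$cvs
  k <- length(cvs$modulus)
  ord <- order(cvs$stretch, cvs$start)
  frag_of <- rep(NA_integer_, k)
  tab <- NULL
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    frag_of[f$cv_idx] <- i
    tab <- rbind(tab, data.frame(stretch = f$stretch, start = f$start,
                                 end = f$end, label = f$label,
                                 n_cv = length(f$cv_idx)))
  }
  structure(list(
    moduli = cvs$modulus[ord],
    labels = annotation$cv_scores$label[ord],
    angle = annotation$graph$angle[ord, ord, drop = FALSE],
    dist = annotation$graph$dist[ord, ord, drop = FALSE],
    frag = frag_of[ord], stretch = cvs$stretch[ord], start = cvs$start[ord],
    fragments = tab, cv_idx = ord,
    annotation = annotation), class = "fold_matrix")
}

#' @export
print.fold_matrix <- function(x, ...) {
  cat(sprintf("<fold_matrix> order %d (%d fragments: %s)\n", length(x$moduli),
              nrow(x$fragments), paste(x$fragments$label, collapse = " ")))
  invisible(x)
}

#' Similarity between two fold-matrix blocks, percent
#'
#' The fraction of compared cells agreeing within the tolerance bands. For
#' an intra-fragment block the cells are each CV's modulus (diagonal) plus
#' every unordered CV pair's (angle, distance); for an inter-fragment block
#' they are all CV pairs across the two fragments. Cells involving a
#' coil-labelled CV are compared with doubled tolerances, so relations in
#' coil regions weigh less strictly.
#'
#' @param fm_a,fm_b `fold_matrix` objects
#' @param idx_a,idx_b CV index vectors (equal length) into each matrix
#' @param intra intra-fragment block (include moduli diagonal)?
#' @param angle_tol,dist_tol,modulus_tol full-credit tolerance bands
#' @return list with `score` (percent), `matched`, `cells`
#' @export
block_similarity <- function(fm_a, idx_a, fm_b, idx_b, intra = TRUE,
                             angle_tol = 15, dist_tol = 2, modulus_tol = 0.5) {
  m <- length(idx_a)
  stopifnot(length(idx_b) == m)
  coil_a <- fm_a$labels[idx_a] == "coil"
  coil_b <- fm_b$labels[idx_b] == "coil"
  matched <- 0L; cells <- 0L
  if (intra) {
    for (p in seq_len(m)) {
      mult <- if (coil_a[p] || coil_b[p]) 2 else 1
      cells <- cells + 1L
      if (abs(fm_a$moduli[idx_a[p]] - fm_b$moduli[idx_b[p]]) <= modulus_tol * mult) {
        matched <- matched + 1L
      }
    }
    if (m > 1) for (p in 1:(m - 1)) for (q in (p + 1):m) {
      mult <- if (coil_a[p] || coil_a[q] || coil_b[p] || coil_b[q]) 2 else 1
      cells <- cells + 1L
      ok_a <- abs(fm_a$angle[idx_a[p], idx_a[q]] -
                    fm_b$angle[idx_b[p], idx_b[q]]) <= angle_tol * mult
      ok_d <- abs(fm_a$dist[idx_a[p], idx_a[q]] -
                    fm_b$dist[idx_b[p], idx_b[q]]) <= dist_tol * mult
      if (isTRUE(ok_a) && ok_d) matched <- matched + 1L
    }
  }
  list(score = if (cells) 100 * matched / cells else 100,
       matched = matched, cells = cells)
}

# Matched/total inter-fragment cells between two assigned windows.
inter_cells <- function(fm_t, idx_t1, idx_t2, fm_g, idx_g1, idx_g2,
                        angle_tol = 15, dist_tol = 2) {
  matched <- 0L
  coil_t1 <- fm_t$labels[idx_t1] == "coil"
  coil_t2 <- fm_t$labels[idx_t2] == "coil"
  for (p in seq_along(idx_t1)) for (q in seq_along(idx_t2)) {
    mult <- if (coil_t1[p] || coil_t2[q]) 2 else 1
    ok_a <- abs(fm_t$angle[idx_t1[p], idx_t2[q]] -
                  fm_g$angle[idx_g1[p], idx_g2[q]]) <= angle_tol * mult
    ok_d <- abs(fm_t$dist[idx_t1[p], idx_t2[q]] -
                  fm_g$dist[idx_g1[p], idx_g2[q]]) <= dist_tol * mult
    if (isTRUE(ok_a) && ok_d) matched <- matched + 1L
  }
  matched
}

#' Find all occurrences of a template fold in a target structure
#'
#' Depth-first recursive search over the fragment assignments: level k
#' proposes every window of consecutive target CVs (inside one same-type
#' target fragment) whose intra-fragment block similarity reaches
#' `ss_threshold`; branches are pruned with an admissible bound on the
#' aggregate inter-fragment (tertiary) similarity -- a branch is discarded
#' only when even a perfect completion could not reach `tt_threshold` -- so
#' every assignment satisfying both thresholds is returned. Fragments may
#' appear reordered or separated by insertions unless
#' `require_connectivity`, which enforces the template's N-to-C fragment
#' order in the target.
#'
#' @param template,target `fold_matrix` objects
#' @param ss_threshold secondary-structure (intra-fragment) threshold, percent
#' @param tt_threshold tertiary-structure (inter-fragment) threshold, percent
#' @param require_connectivity enforce template fragment order
#' @param angle_tol,dist_tol,modulus_tol comparison bands
#' @return list of `fold_match` objects with `assignment` (template/target
#'   residue correspondence per fragment), `ss_score`, `tt_score`,
#'   `connectivity_ok`
#' @export
find_fold_occurrences <- function(template, target, ss_threshold = 45,
                                  tt_threshold = 55,
                                  require_connectivity = FALSE,
                                  angle_tol = 15, dist_tol = 2,
                                  modulus_tol = 0.5) {
  stopifnot(ss_threshold >= 0, ss_threshold <= 100,
            tt_threshold >= 0, tt_threshold <= 100)
  nf <- nrow(template$fragments)
  t_cvs <- lapply(seq_len(nf), function(i) which(template$frag == i))
  window <- template$annotation$cvs$window

  # Candidate windows per template fragment: any run of m consecutive CVs
  # of one target stretch whose majority carries the fragment's label.
  # Working over all CVs (not only those inside annotated fragments) makes
  # the search robust to fragments that the strictness threshold shrank or
  # split; the similarity thresholds do the actual discrimination.
  candidates <- lapply(seq_len(nf), function(i) {
    m <- length(t_cvs[[i]])
    lab <- template$fragments$label[i]
    out <- list()
    for (s in unique(target$stretch)) {
      pos <- which(target$stretch == s)
      pos <- pos[order(target$start[pos])]
      if (length(pos) < m) next
      for (off in 0:(length(pos) - m)) {
        idx <- pos[(off + 1):(off + m)]
        if (sum(target$labels[idx] == lab) < ceiling(m / 2)) next
        bs <- block_similarity(template, t_cvs[[i]], target, idx,
                               intra = TRUE, angle_tol = angle_tol,
                               dist_tol = dist_tol, modulus_tol = modulus_tol)
        if (bs$score >= ss_threshold) {
          fr <- target$frag[idx]
          fr <- fr[!is.na(fr)]
          out[[length(out) + 1L]] <- list(
            frag = if (length(fr)) as.integer(names(which.max(table(fr))))
                   else NA_integer_,
            idx = idx, stretch = s,
            res_start = target$start[idx[1]],
            res_end = target$start[idx[m]] + window - 1L,
            ss_matched = bs$matched, ss_cells = bs$cells)
        }
      }
    }
    out
  })
  if (any(vapply(candidates, length, 1L) == 0)) return(list())

  cells_of_pair <- outer(vapply(t_cvs, length, 1L), vapply(t_cvs, length, 1L))
  total_inter <- if (nf > 1) sum(cells_of_pair[upper.tri(cells_of_pair)]) else 0L

  matches <- list()
  assign_rows <- vector("list", nf)
  dfs <- function(level, matched_inter, cells_done) {
    if (level > nf) {
      tt <- if (total_inter > 0) 100 * matched_inter / total_inter else 100
      if (tt >= tt_threshold) {
        ssm <- sum(vapply(assign_rows, function(a) a$ss_matched, 1L))
        ssc <- sum(vapply(assign_rows, function(a) a$ss_cells, 1L))
        matches[[length(matches) + 1L]] <<- make_fold_match(
          template, target, assign_rows, 100 * ssm / ssc, tt, window)
      }
      return(invisible())
    }
    for (cand in candidates[[level]]) {
      ok <- TRUE
      add <- 0L
      for (prev in seq_len(level - 1L)) {
        pr <- assign_rows[[prev]]
        # residue overlap in the target
        if (pr$stretch == cand$stretch &&
            pr$res_start <= cand$res_end && cand$res_start <= pr$res_end) {
          ok <- FALSE; break
        }
        if (require_connectivity &&
            !(pr$stretch < cand$stretch ||
              (pr$stretch == cand$stretch && pr$res_end < cand$res_start))) {
          ok <- FALSE; break
        }
        add <- add + inter_cells(template, t_cvs[[prev]], t_cvs[[level]],
                                 target, pr$idx, cand$idx,
                                 angle_tol, dist_tol)
      }
      if (!ok) next
      new_cells <- cells_done + sum(cells_of_pair[seq_len(level - 1L), level])
      bound <- if (total_inter > 0) {
        100 * (matched_inter + add + (total_inter - new_cells)) / total_inter
      } else 100
      if (bound < tt_threshold) next
      assign_rows[[level]] <<- cand
      dfs(level + 1L, matched_inter + add, new_cells)
    }
  }
  dfs(1L, 0L, 0L)
  matches
}

make_fold_match <- function(template, target, assign_rows, ss, tt, window) {
  tab <- do.call(rbind, lapply(seq_along(assign_rows), function(i) {
    a <- assign_rows[[i]]
    data.frame(template_stretch = template$fragments$stretch[i],
               template_start = template$fragments$start[i],
               template_end = template$fragments$end[i],
               target_stretch = a$stretch,
               target_start = a$res_start, target_end = a$res_end,
               length = a$res_end - a$res_start + 1L,
               target_fragment = a$frag)
  }))
  conn <- all(diff(order(tab$target_stretch * 1e6 + tab$target_start)) == 1) &&
    !is.unsorted(tab$target_stretch * 1e6 + tab$target_start)
  structure(list(assignment = tab, ss_score = ss, tt_score = tt,
                 connectivity_ok = conn, source = target$annotation$structure$source,
                 rmsd_to_template = NA_real_),
            class = "fold_match")
}

#' @export
print.fold_match <- function(x, ...) {
  cat(sprintf("<fold_match> %d fragments, ss %.1f%%, tt %.1f%%, rmsd %s\n",
              nrow(x$assignment), x$ss_score, x$tt_score,
              ifelse(is.na(x$rmsd_to_template), "-",
                     sprintf("%.2f A", x$rmsd_to_template))))
  invisible(x)
}

one_letter <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
                MSE = "M")

# CA pairing of a match (template reference, target mobile).
match_ca_pairing <- function(match, ann_t, ann_g) {
  a <- b <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(match$assignment))) {
    r <- match$assignment[i, ]
    b <- rbind(b, ann_t$structure$stretches[[r$template_stretch]]$xyz$CA[
      r$template_start:r$template_end, , drop = FALSE])
    a <- rbind(a, ann_g$structure$stretches[[r$target_stretch]]$xyz$CA[
      r$target_start:r$target_end, , drop = FALSE])
  }
  list(target = a, template = b)
}

#' Filter fold matches by sequence, disulfide and r.m.s.d.
#'
#' @param matches list of `fold_match`
#' @param ann_t,ann_g the template and target `cv_annotation`s
#' @param sequence_pattern optional one-letter pattern matched position-wise
#'   against the match residues in template fragment order; `X` matches any
#'   residue; its length must equal the template size in residues
#' @param disulfide require an S-gamma pair within `disulfide_window` among
#'   the matched residues
#' @param disulfide_window S-gamma--S-gamma distance bounds, Angstrom
#' @param max_rmsd keep matches whose CA r.m.s.d. to the template (after
#'   optimal superposition) does not exceed this bound; also fills
#'   `rmsd_to_template`
#' @return the filtered list (each kept match gains `rmsd_to_template`)
#' @export
apply_filters <- function(matches, ann_t, ann_g, sequence_pattern = NULL,
                          disulfide = FALSE, disulfide_window = c(1.8, 2.5),
                          max_rmsd = NULL) {
  keep <- list()
  for (m in matches) {
    if (!is.null(sequence_pattern)) {
      res <- unlist(lapply(seq_len(nrow(m$assignment)), function(i) {
        r <- m$assignment[i, ]
        ann_g$structure$stretches[[r$target_stretch]]$resname[
          r$target_start:r$target_end]
      }))
      pat <- strsplit(toupper(sequence_pattern), "")[[1]]
      if (length(pat) != length(res)) {
        stop("sequence pattern length (", length(pat),
             ") must equal template size (", length(res), ")")
      }
      aa <- unname(one_letter[res])
      aa[is.na(aa)] <- "?"
      if (!all(pat == "X" | pat == aa)) next
    }
    if (disulfide) {
      sg <- do.call(rbind, lapply(seq_len(nrow(m$assignment)), function(i) {
        r <- m$assignment[i, ]
        ann_g$structure$stretches[[r$target_stretch]]$sg[
          r$target_start:r$target_end, , drop = FALSE]
      }))
      sg <- sg[!is.na(sg[, 1]), , drop = FALSE]
      ok <- FALSE
      if (nrow(sg) >= 2) {
        d <- as.matrix(stats::dist(sg))
        dd <- d[upper.tri(d)]
        ok <- any(dd >= disulfide_window[1] & dd <= disulfide_window[2])
      }
      if (!ok) next
    }
    pc <- match_ca_pairing(m, ann_t, ann_g)
    m$rmsd_to_template <- kabsch_rmsd(pc$target, pc$template)$rmsd
    if (!is.null(max_rmsd) && m$rmsd_to_template > max_rmsd + 1e-9) next
    keep[[length(keep) + 1L]] <- m
  }
  keep
}

# Extract a match as a structure (backbone + SG), superposed on the template.
extract_match_model <- function(match, ann_t, ann_g,
                                atoms = c("N", "CA", "C", "O")) {
  pc <- match_ca_pairing(match, ann_t, ann_g)
  fit <- weighted_refine(pc$target, pc$template)
  stretches <- lapply(seq_len(nrow(match$assignment)), function(i) {
    r <- match$assignment[i, ]
    st <- ann_g$structure$stretches[[r$target_stretch]]
    sel <- r$target_start:r$target_end
    new_stretch(chain = st$chain, resno = st$resno[sel],
                resname = st$resname[sel], ins = st$ins[sel],
                xyz = lapply(st$xyz, function(m) m[sel, , drop = FALSE]),
                b = st$b[sel, , drop = FALSE],
                sg = st$sg[sel, , drop = FALSE],
                provenance = st$provenance)
  })
  model <- new_structure(stretches, source = ann_g$structure$source,
                         model = ann_g$structure$model)
  transform_structure(model, fit$rotation, fit$translation)
}

#' Generate a library of fold occurrences
#'
#' The five-step pipeline: annotate the template and every structure in the
#' database, extract all occurrences of the template fold with the
#' recursive search, filter (sequence / disulfide / maximum r.m.s.d.),
#' superpose every surviving model onto the template with a common B
#' factor, and write the models into `out_dir/library` named
#' `pdbid_x_yyyy.pdb` (source identifier, model index -- 0 except for
#' multi-model entries -- and a four-digit counter).
#'
#' @param template path to the template PDB (or a `cv_structure`)
#' @param database a directory of PDB files, or a vector of paths
#' @param out_dir output directory (gets a `library/` subdirectory)
#' @param ss_threshold,tt_threshold search thresholds, percent
#' @param strictness_ah,strictness_bs annotation strictness
#' @param max_rmsd r.m.s.d. cutoff to the template, Angstrom
#' @param sequence_pattern,disulfide optional filters (see [apply_filters()])
#' @param require_connectivity enforce template fragment order
#' @param multi_chain search all chains (otherwise one representative of
#'   equivalent monomers)
#' @param b_factor common B factor written into every model
#' @param id_list optional file of source identifiers (one per line): only
#'   database entries whose file stem is listed are searched
#' @return manifest data.frame (file, source, model ss/tt scores, r.m.s.d.)
#' @export
generate_library <- function(template, database, out_dir = ".",
                             ss_threshold = 45, tt_threshold = 55,
                             strictness_ah = 0.5, strictness_bs = 0.3,
                             max_rmsd = 5.0, sequence_pattern = NULL,
                             disulfide = FALSE, require_connectivity = FALSE,
                             multi_chain = FALSE, b_factor = 25.0,
                             id_list = NULL) {
  if (is.character(template)) template <- parse_structure(template)
  files <- if (length(database) == 1 && dir.exists(database)) {
    list.files(database, pattern = "\\.(pdb|ent)$", full.names = TRUE)
  } else database
  if (!is.null(id_list)) {
    ids <- tolower(trimws(readLines(id_list)))
    stem <- tolower(sub("\\.(pdb|ent)$", "", basename(files)))
    files <- files[stem %in% ids]
  }
  lib_dir <- file.path(out_dir, "library")
  dir.create(lib_dir, recursive = TRUE, showWarnings = FALSE)
  ann_t <- annotate_structure(template, strictness_ah, strictness_bs)
  if (length(ann_t$fragments) == 0) {
    stop("unusable template: no secondary-structure fragment annotated")
  }
  fm_t <- build_fold_matrix(ann_t)
  manifest <- NULL
  for (f in files) {
    strc <- tryCatch(parse_structure(f, keep_all_chains = multi_chain),
                     error = function(e) NULL)
    if (is.null(strc)) next
    ann_g <- annotate_structure(strc, strictness_ah, strictness_bs)
    if (length(ann_g$fragments) == 0) next
    fm_g <- build_fold_matrix(ann_g)
    matches <- find_fold_occurrences(fm_t, fm_g, ss_threshold, tt_threshold,
                                     require_connectivity = require_connectivity)
    matches <- apply_filters(matches, ann_t, ann_g,
                             sequence_pattern = sequence_pattern,
                             disulfide = disulfide, max_rmsd = max_rmsd)
    pdbid <- tolower(sub("\\.(pdb|ent)$", "", basename(f)))
    ctr <- 0L
    for (m in matches) {
      ctr <- ctr + 1L
      model <- extract_match_model(m, ann_t, ann_g)
      fname <- sprintf("%s_%d_%04d.pdb", pdbid, strc$model - 1L, ctr)
      write_structure(model, file.path(lib_dir, fname),
                      b_factor_override = b_factor)
      manifest <- rbind(manifest, data.frame(
        file = fname, source = f, model_index = strc$model - 1L,
        ss_score = m$ss_score, tt_score = m$tt_score,
        rmsd_to_template = m$rmsd_to_template))
    }
  }
  manifest %||% data.frame(file = character(0), source = character(0),
                           model_index = integer(0), ss_score = numeric(0),
                           tt_score = numeric(0),
                           rmsd_to_template = numeric(0))
}

#' Cluster a model library
#'
#' Three modes: `pairwise_rmsd` groups models by complete-linkage
#' hierarchical clustering of all pairwise r.m.s.d.s (after optimal
#' superposition of each pair), cut at `rmsd_cut` -- deterministic and the
#' finest criterion; `rmsd_range` bins models by their r.m.s.d. to the
#' template (from the manifest); `random_subset` draws a seeded sample.
#'
#' @param lib_dir the `library/` directory of [generate_library()]
#' @param manifest the manifest returned by [generate_library()]
#' @param mode clustering mode
#' @param rmsd_cut complete-linkage cut, Angstrom
#' @param breaks bin boundaries for `rmsd_range`
#' @param n subset size for `random_subset`
#' @param seed RNG seed for `random_subset`
#' @param clusters_dir optional: copy models into per-cluster directories
#' @return integer cluster id per manifest row (for `random_subset`, 1 for
#'   selected models and NA otherwise)
#' @export
cluster_library <- function(lib_dir, manifest,
                            mode = c("pairwise_rmsd", "rmsd_range",
                                     "random_subset"),
                            rmsd_cut = 1.0, breaks = c(0, 1, 2, 5, Inf),
                            n = 10L, seed = 42L, clusters_dir = NULL) {
  mode <- match.arg(mode)
  nm <- nrow(manifest)
  if (nm == 0) return(integer(0))
  if (mode == "pairwise_rmsd") {
    coords <- lapply(file.path(lib_dir, manifest$file), function(f) {
      strc <- parse_structure(f)
      do.call(rbind, lapply(strc$stretches, function(s) s$xyz$CA))
    })
    if (nm == 1) {
      cl <- 1L
    } else {
      D <- matrix(0, nm, nm)
      for (i in 1:(nm - 1)) for (j in (i + 1):nm) {
        D[i, j] <- D[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]])$rmsd
      }
      hc <- stats::hclust(stats::as.dist(D), method = "complete")
      cl <- stats::cutree(hc, h = rmsd_cut)
    }
  } else if (mode == "rmsd_range") {
    cl <- as.integer(cut(manifest$rmsd_to_template, breaks = breaks,
                         include.lowest = TRUE))
  } else {
    set.seed(seed)
    pick <- sample(nm, min(n, nm))
    cl <- rep(NA_integer_, nm)
    cl[pick] <- 1L
  }
  if (!is.null(clusters_dir)) {
    for (k in unique(cl[!is.na(cl)])) {
      d <- file.path(clusters_dir, sprintf("cluster_%d", k))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (f in manifest$file[which(cl == k)]) {
        file.copy(file.path(lib_dir, f), file.path(d, f), overwrite = TRUE)
      }
    }
  }
  cl
}
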