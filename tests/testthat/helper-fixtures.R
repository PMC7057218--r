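# Shared fixture builders and independent oracles for the test suite.

# Two strands + one helix, the standard composite local fold used across
# the fold-search and library tests. Spans three chains by construction.
fold_fixture <- function() {
  els <- c(sheet_elements("UD", length = 7, spacing = 4.8),
           list(element("ah", 9, t = c(0, 2.4, 9))))
  assemble_fold(els)
}

# Two-domain fixture: a helix pair and a distant three-strand sheet.
two_domain_fixture <- function() {
  els <- c(list(element("ah", 10, t = c(0, 0, 0), group = 1),
                element("ah", 10, t = c(0, 10, 0), group = 1)),
           lapply(sheet_elements("UDU", 8, group = 2), function(e) {
             e$t <- e$t + c(40, 0, 0)
             e
           }))
  assemble_fold(els)
}

# Hand-built stretch from explicit atom matrices (defaults keep unused
# atoms out of the way but finite).
manual_stretch <- function(ca, o, n = NULL, c = NULL) {
  k <- nrow(ca)
  if (is.null(n)) n <- ca + matrix(rep(c(-0.5, 0.8, 0), k), k, byrow = TRUE)
  if (is.null(c)) c <- ca + matrix(rep(c(0.9, 0.6, 0), k), k, byrow = TRUE)
  new_stretch("A", seq_len(k), rep("ALA", k),
              list(N = n, CA = ca, C = c, O = o))
}

# Brute-force fold-search oracle: enumerate every combination of candidate
# windows (same candidate definition as the search: majority-label runs of
# consecutive CVs whose intra-block similarity passes ss_threshold), keep
# combinations with non-overlapping residues, optional connectivity, and an
# aggregate inter-fragment similarity >= tt_threshold. Independent of the
# recursive implementation: no pruning, plain loops over the full product.
brute_force_fold_search <- function(fm_t, fm_g, ss_threshold, tt_threshold,
                                    require_connectivity = FALSE) {
  nf <- nrow(fm_t$fragments)
  t_cvs <- lapply(seq_len(nf), function(i) which(fm_t$frag == i))
  cand <- lapply(seq_len(nf), function(i) {
    m <- length(t_cvs[[i]])
    lab <- fm_t$fragments$label[i]
    out <- list()
    for (s in unique(fm_g$stretch)) {
      pos <- which(fm_g$stretch == s)
      pos <- pos[order(fm_g$start[pos])]
      if (length(pos) < m) next
      for (off in 0:(length(pos) - m)) {
        idx <- pos[(off + 1):(off + m)]
        if (sum(fm_g$labels[idx] == lab) < ceiling(m / 2)) next
        bs <- block_similarity(fm_t, t_cvs[[i]], fm_g, idx)
        if (bs$score >= ss_threshold) {
          out[[length(out) + 1L]] <- list(idx = idx, stretch = s,
                                          res_start = fm_g$start[idx[1]],
                                          res_end = fm_g$start[idx[m]] + 2L)
        }
      }
    }
    out
  })
  if (any(vapply(cand, length, 1L) == 0)) return(character(0))
  grid <- expand.grid(lapply(cand, seq_along))
  keys <- character(0)
  for (r in seq_len(nrow(grid))) {
    sel <- lapply(seq_len(nf), function(i) cand[[i]][[grid[r, i]]])
    ok <- TRUE
    if (nf > 1) for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      a <- sel[[i]]; b <- sel[[j]]
      if (a$stretch == b$stretch &&
          a$res_start <= b$res_end && b$res_start <= a$res_end) ok <- FALSE
      if (require_connectivity && j == i + 1 &&
          !(a$stretch < b$stretch ||
            (a$stretch == b$stretch && a$res_end < b$res_start))) ok <- FALSE
    }
    if (!ok) next
    matched <- 0; total <- 0
    if (nf > 1) for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      for (p in seq_along(sel[[i]]$idx)) for (q in seq_along(sel[[j]]$idx)) {
        ti <- which(fm_t$frag == i)[p]; tj <- which(fm_t$frag == j)[q]
        mult <- if (fm_t$labels[ti] == "coil" || fm_t$labels[tj] == "coil") 2 else 1
        ok_a <- abs(fm_t$angle[ti, tj] -
                      fm_g$angle[sel[[i]]$idx[p], sel[[j]]$idx[q]]) <= 15 * mult
        ok_d <- abs(fm_t$dist[ti, tj] -
                      fm_g$dist[sel[[i]]$idx[p], sel[[j]]$idx[q]]) <= 2 * mult
        if (isTRUE(ok_a) && ok_d) matched <- matched + 1
        total <- total + 1
      }
    }
    tt <- if (total > 0) 100 * matched / total else 100
    if (tt >= tt_threshold) {
      keys <- c(keys, paste(vapply(sel, function(x) {
        paste(x$stretch, x$res_start, x$res_end, sep = ":")
      }, ""), collapse = "|"))
    }
  }
  sort(unique(keys))
}

# Canonical key of a recursive-search match, comparable to the oracle's.
match_key <- function(m) {
  paste(paste(m$assignment$target_stretch, m$assignment$target_start,
              m$assignment$target_end, sep = ":"), collapse = "|")
}

# Random small target containing the fold fixture plus decoys; used for the
# search-completeness properties.
random_search_target <- function(seed) {
  set.seed(seed)
  n_extra <- sample(0:3, 1)
  els <- c(sheet_elements("UD", length = 7, spacing = 4.8),
           list(element("ah", 9, t = c(0, 2.4, 9))))
  if (n_extra > 0) {
    extra <- lapply(seq_len(n_extra), function(i) {
      element(sample(c("ah", "bs"), 1), sample(6:10, 1),
              R = random_rotation(),
              t = c(25 + 14 * i, stats::rnorm(1, sd = 5), stats::rnorm(1, sd = 5)))
    })
    els <- c(els, extra)
  }
  assemble_fold(els, noise_sigma = stats::runif(1, 0, 0.2), seed = seed + 500L)
}
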