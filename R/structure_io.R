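#' Read a structure from a PDB file
#'
#' Parsing enforces the rules the CV machinery relies on: waters are
#' discarded; for every atom only the highest-occupancy alternate location
#' is kept (ties broken by the lowest altloc letter); residues missing any
#' of the four main-chain atoms N, CA, C, O are dropped entirely; and chain
#' connectivity is established by the C(i)--N(i+1) peptide-bond distance
#' test (1.1--1.8 A accepted) rather than by residue numbering, so
#' renumbered or broken chains split into the geometrically correct
#' stretches. Cysteine S-gamma atoms are retained for the disulfide filter.
#'
#' @param path PDB file
#' @param model_index model to read (1-based; PDB MODEL records)
#' @param keep_all_chains keep every chain (`TRUE`, default) or drop
#'   equivalent monomers (chains with an identical residue sequence),
#'   keeping the first by order of appearance
#' @return a `cv_structure`
#' @export
parse_structure <- function(path, model_index = 1L, keep_all_chains = TRUE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model_index > 1,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("not a readable PDB file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  at <- pdb$atom
  if (model_index > 1) {
    n_models <- nrow(pdb$xyz)
    if (model_index > n_models || ncol(pdb$xyz) != 3 * nrow(at)) {
      stop("model ", model_index, " not present in ", path)
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD", "H2O")), , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O", "SG"), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  if (nrow(at) == 0) stop("empty structure: no usable residues in ", path)

  # one altloc per atom: highest occupancy, then lowest altloc letter
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert)
  have <- tapply(at$elety, rkey, function(e) all(c("N", "CA", "C", "O") %in% e))
  at <- at[have[rkey], , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no complete main-chain residues in ", path)

  res <- unique(at[, c("chain", "resno", "insert", "resid")])
  # insertion codes sort after their base number
  res <- res[order(res$chain, res$resno, res$insert), , drop = FALSE]
  rk <- paste(res$chain, res$resno, res$insert)
  coord <- function(elety) {
    sub <- at[at$elety == elety, , drop = FALSE]
    m <- matrix(NA_real_, nrow(res), 3)
    i <- match(paste(sub$chain, sub$resno, sub$insert), rk)
    m[i, ] <- cbind(sub$x, sub$y, sub$z)
    m
  }
  bcol <- function(elety) {
    sub <- at[at$elety == elety, , drop = FALSE]
    v <- rep(0, nrow(res))
    v[match(paste(sub$chain, sub$resno, sub$insert), rk)] <- sub$b
    v
  }
  xyzl <- list(N = coord("N"), CA = coord("CA"), C = coord("C"), O = coord("O"))
  sg <- coord("SG")
  bmat <- cbind(bcol("N"), bcol("CA"), bcol("C"), bcol("O"))

  stretches <- list()
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    if (length(idx) == 0) next
    brk <- if (length(idx) > 1) {
      d <- rowdist(xyzl$C[idx[-length(idx)], , drop = FALSE],
                   xyzl$N[idx[-1], , drop = FALSE])
      which(d < 1.1 | d > 1.8)
    } else integer(0)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(idx))
    for (s in seq_along(starts)) {
      sel <- idx[starts[s]:ends[s]]
      stretches[[length(stretches) + 1L]] <- new_stretch(
        chain = ch, resno = res$resno[sel], resname = res$resid[sel],
        ins = res$insert[sel],
        xyz = lapply(xyzl, function(m) m[sel, , drop = FALSE]),
        b = bmat[sel, , drop = FALSE],
        sg = sg[sel, , drop = FALSE],
        provenance = list(source = path, model = model_index, chain = ch))
    }
  }
  out <- new_structure(stretches, source = path, model = model_index)
  if (!keep_all_chains) out <- representative_chains(out)
  out
}

#' Drop equivalent monomers, keeping one representative per sequence
#'
#' Chains whose stretches carry an identical residue-name sequence are
#' considered equivalent copies; the first by order of appearance is kept.
#'
#' @param structure a `cv_structure`
#' @return the reduced `cv_structure`
#' @export
representative_chains <- function(structure) {
  chains <- vapply(structure$stretches, function(s) s$chain, "")
  sig <- vapply(unique(chains), function(ch) {
    paste(unlist(lapply(structure$stretches[chains == ch],
                        function(s) s$resname)), collapse = "")
  }, "")
  keep_chains <- unique(chains)[!duplicated(sig)]
  structure$stretches <- structure$stretches[chains %in% keep_chains]
  structure
}

#' Write a structure to a PDB file
#'
#' @param structure a `cv_structure` (or a single `cv_stretch`)
#' @param path output file
#' @param chain_override optional: either a character vector with one chain
#'   id per stretch, or a list of per-residue chain-id vectors (one per
#'   stretch), as produced by the fold decomposition
#' @param b_factor_override optional constant written into every B-factor
#'   field (e.g. the common B factor of library models)
#' @return `path`, invisibly
#' @export
write_structure <- function(structure, path, chain_override = NULL,
                            b_factor_override = NULL) {
  if (inherits(structure, "cv_stretch")) structure <- new_structure(list(structure))
  eleno <- resno <- o <- b <- numeric(0)
  elety <- resid <- chain <- insert <- character(0)
  xyz <- numeric(0)
  ctr <- 0L
  for (s in seq_along(structure$stretches)) {
    st <- structure$stretches[[s]]
    n <- length(st$resno)
    ch <- if (is.null(chain_override)) rep(st$chain, n)
          else if (is.list(chain_override)) chain_override[[s]]
          else rep(chain_override[s], n)
    for (i in seq_len(n)) {
      names4 <- c("N", "CA", "C", "O")
      has_sg <- !is.na(st$sg[i, 1])
      nm <- if (has_sg) c(names4, "SG") else names4
      for (a in nm) {
        ctr <- ctr + 1L
        eleno <- c(eleno, ctr)
        elety <- c(elety, a)
        resid <- c(resid, st$resname[i])
        chain <- c(chain, ch[i])
        resno <- c(resno, st$resno[i])
        insert <- c(insert, st$ins[i])
        o <- c(o, 1)
        bv <- if (!is.null(b_factor_override)) b_factor_override
              else if (a == "SG") st$b[i, 4] else st$b[i, match(a, names4)]
        b <- c(b, bv)
        p <- if (a == "SG") st$sg[i, ] else st$xyz[[a]][i, ]
        xyz <- c(xyz, p)
      }
    }
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates; refusing to write")
  insert[insert == ""] <- NA
  suppressWarnings(bio3d::write.pdb(file = path, xyz = xyz, eleno = eleno,
                                    elety = elety, resid = resid,
                                    chain = chain, resno = resno,
                                    insert = insert, o = o, b = b))
  invisible(path)
}
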