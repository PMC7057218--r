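#' Synthetic backbone fixtures with known ground truth
#'
#' Structures are built in internal (torsion) coordinates and converted to
#' Cartesian coordinates by sequential atom placement (NeRF), so the
#' phi/psi/omega values are exact by construction. Canonical torsions:
#' alpha-helix phi = -57, psi = -47; beta-strand phi = -139, psi = +135
#' (with an alternating +/- 5 degree psi pleat available to mimic real
#' sheets); omega = 180 throughout. Ideal bond geometry follows standard
#' main-chain values (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A).
#'
#' @name fixtures
NULL

.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

.canonical <- list(
  ah = c(phi = -57, psi = -47),
  bs = c(phi = -139, psi = 135)
)

# Irregular torsion cycle far from both ideal regions; used for coil.
.coil_torsions <- matrix(c(
  -80,  70,
  -150,  55,
  -70, 155,
   60,  40,
  -100, -10
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("phi", "psi")))

# Place atom D given the three preceding atoms and internal coordinates.
place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  d2 <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  C + cbind(bc, m, n) %*% d2
}

# Build N/CA/C/O coordinates for n residues from per-residue torsions.
build_backbone <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  if (is.null(omega)) omega <- rep(180, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$b_n_ca, 0, 0)
  ang <- .bb$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .bb$b_ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  if (n > 1) {
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           .bb$b_c_n, .bb$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            .bb$b_n_ca, .bb$a_c_n_ca, omega[i - 1])
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           .bb$b_ca_c, .bb$a_n_ca_c, phi[i])
    }
  }
  # Carbonyl O: in the peptide plane, anti to the following N (torsion psi + 180).
  for (i in 1:n) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         .bb$b_c_o, .bb$a_ca_c_o, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Per-residue torsions for one secondary-structure element.
element_torsions <- function(type, length, pleat = 5) {
  if (type == "ah") {
    phi <- rep(.canonical$ah["phi"], length)
    psi <- rep(.canonical$ah["psi"], length)
  } else if (type == "bs") {
    phi <- rep(.canonical$bs["phi"], length)
    psi <- .canonical$bs["psi"] + pleat * rep(c(1, -1), length.out = length)
  } else if (type == "coil") {
    idx <- rep(seq_len(nrow(.coil_torsions)), length.out = length)
    phi <- .coil_torsions[idx, "phi"]
    psi <- .coil_torsions[idx, "psi"]
  } else {
    stop("unknown element type: ", type)
  }
  list(phi = unname(phi), psi = unname(psi))
}

#' Build an ideal secondary-structure element
#'
#' @param type one of `"ah"`, `"bs"`, `"coil"`
#' @param length number of residues (>= 3)
#' @param chain chain identifier
#' @param start_resno residue number of the first residue
#' @param pleat psi alternation amplitude in degrees for strands; 0 gives a
#'   geometrically exact repeat of the canonical torsions
#' @param resname residue type(s): a single code (poly-Ala by default) or a
#'   vector of `length` three-letter codes
#' @return a [new_stretch()] object
#' @export
#' @examples
#' hx <- build_ideal_element("ah", 12)
#' cvs <- compute_cvs(hx)
#' mean(cvs$modulus)   # ~2.2 A for a helix
build_ideal_element <- function(type, length, chain = "A", start_resno = 1L,
                                pleat = 5, resname = "ALA") {
  stopifnot(length >= 3)
  tor <- element_torsions(type, length, pleat = pleat)
  bb <- canonicalize_backbone(build_backbone(tor$phi, tor$psi))
  resname <- if (length(resname) == 1) rep(resname, length) else resname
  stopifnot(length(resname) == length)
  new_stretch(chain = chain, resno = start_resno + seq_len(length) - 1L,
              resname = resname, xyz = bb,
              provenance = list(source = "fixture", model = 0L, chain = chain,
                                type = type))
}

# Rotation taking unit vector a onto unit vector b (Rodrigues).
align_rotation <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  v <- cross3(a, b)
  s <- sqrt(sum(v^2)); c <- sum(a * b)
  if (s < 1e-12) {
    if (c > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about_axis(p, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c) / s^2)
}

# Put a built element into a canonical frame: CA centroid at the origin,
# chain axis (first-to-last CA) along +x, mean carbonyl offset in the +y
# half of the xy-plane. Placement transforms in fixtures then have a
# predictable meaning (e.g. sheets stack along y).
canonicalize_backbone <- function(bb) {
  ctr <- colMeans(bb$CA)
  bb <- lapply(bb, function(m) sweep(m, 2, ctr))
  axis <- bb$CA[nrow(bb$CA), ] - bb$CA[1, ]
  R1 <- align_rotation(axis, c(1, 0, 0))
  bb <- lapply(bb, function(m) m %*% t(R1))
  perp <- colMeans(bb$O) - colMeans(bb$CA)
  perp[1] <- 0
  if (sqrt(sum(perp^2)) < 1e-6) {
    perp <- bb$CA[1, ]; perp[1] <- 0
  }
  R2 <- align_rotation(perp, c(0, 1, 0))
  lapply(bb, function(m) m %*% t(R2))
}

#' Describe one element of a composite fixture
#'
#' @param type `"ah"`, `"bs"` or `"coil"`
#' @param length residues
#' @param R,t rigid placement (rotation, translation) applied after building
#' @param group optional ground-truth group id (for decomposition fixtures)
#' @export
element <- function(type, length, R = diag(3), t = c(0, 0, 0), group = NA) {
  list(type = type, length = length, R = R, t = t, group = group)
}

#' Elements of an n-strand sheet with U/D (up/down) orientations
#'
#' Strands run along x; successive strands are offset along y by `spacing`.
#' "D" strands are rotated 180 degrees about the sheet normal (z), flipping
#' the chain direction as in an antiparallel sheet.
#'
#' @param pattern string of U and D, e.g. `"UDU"`
#' @param length residues per strand
#' @param spacing inter-strand separation in Angstrom
#' @param group ground-truth group id for all strands
#' @export
sheet_elements <- function(pattern = "UDU", length = 8, spacing = 4.8, group = 1) {
  dirs <- strsplit(pattern, "")[[1]]
  stopifnot(all(dirs %in% c("U", "D")))
  lapply(seq_along(dirs), function(i) {
    R <- if (dirs[i] == "D") rotation_about_axis(c(0, 0, 1), 180) else diag(3)
    element("bs", length, R = R, t = c(0, (i - 1) * spacing, 0), group = group)
  })
}

#' Assemble a composite fixture with ground truth
#'
#' Elements are either placed as separate stretches by their rigid
#' transforms (`joined = FALSE`) or concatenated into one continuous chain
#' with coil linkers built in torsion space (`joined = TRUE`, placement
#' transforms ignored). Ground truth (per-residue labels, element table,
#' sheet membership from construction geometry) is returned alongside.
#'
#' @param elements list of [element()] descriptions (>= 1)
#' @param joined concatenate into a single chain with coil linkers?
#' @param linker_length coil residues between joined elements
#' @param noise_sigma Gaussian coordinate noise, Angstrom (applied last)
#' @param seed seed for the noise
#' @return list with `structure` (a `cv_structure`) and `truth`
#'   (`labels`: list of per-residue label vectors per stretch;
#'    `elements`: data.frame of stretch/start/end/type/group;
#'    `sheets`: ground-truth sheet id per element, NA for non-strands)
#' @export
assemble_fold <- function(elements, joined = FALSE, linker_length = 4,
                          noise_sigma = 0, seed = 1L) {
  if (length(elements) == 0) stop("empty fixture: no elements")
  chains <- c(LETTERS, letters, 0:9)
  if (joined) {
    phi <- psi <- numeric(0)
    lab <- character(0)
    tab <- NULL
    for (i in seq_along(elements)) {
      el <- elements[[i]]
      tor <- element_torsions(el$type, el$length)
      if (i > 1 && linker_length > 0) {
        lt <- element_torsions("coil", linker_length)
        phi <- c(phi, lt$phi); psi <- c(psi, lt$psi)
        lab <- c(lab, rep("coil", linker_length))
      }
      start <- length(phi) + 1L
      phi <- c(phi, tor$phi); psi <- c(psi, tor$psi)
      lab <- c(lab, rep(el$type, el$length))
      tab <- rbind(tab, data.frame(stretch = 1L, start = start,
                                   end = start + el$length - 1L,
                                   type = el$type,
                                   group = el$group %||% NA))
    }
    bb <- build_backbone(phi, psi)
    st <- new_stretch("A", seq_along(phi), rep("ALA", length(phi)), bb,
                      provenance = list(source = "fixture", model = 0L, chain = "A"))
    stretches <- list(st)
    labels <- list(lab)
  } else {
    stretches <- vector("list", length(elements))
    labels <- vector("list", length(elements))
    tab <- NULL
    for (i in seq_along(elements)) {
      el <- elements[[i]]
      st <- build_ideal_element(el$type, el$length, chain = chains[i])
      st <- transform_stretch(st, el$R %||% diag(3), el$t %||% c(0, 0, 0))
      stretches[[i]] <- st
      labels[[i]] <- rep(el$type, el$length)
      tab <- rbind(tab, data.frame(stretch = i, start = 1L, end = el$length,
                                   type = el$type, group = el$group %||% NA))
    }
  }
  truth <- list(labels = labels, elements = tab,
                sheets = truth_sheets(stretches, tab))
  st <- new_structure(stretches, source = "fixture")
  if (noise_sigma > 0) {
    st <- perturb(st, noise_sigma = noise_sigma, seed = seed)
  }
  list(structure = st, truth = truth)
}

# Ground-truth sheet grouping: strand elements whose CA sets approach
# within 6 A are in the same sheet (connected components).
truth_sheets <- function(stretches, tab) {
  sheet <- rep(NA_integer_, nrow(tab))
  is_bs <- tab$type == "bs"
  idx <- which(is_bs)
  if (length(idx) == 0) return(sheet)
  ca <- lapply(idx, function(i) {
    stretches[[tab$stretch[i]]]$xyz$CA[tab$start[i]:tab$end[i], , drop = FALSE]
  })
  k <- length(idx)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- min(sqrt(outer(rowSums(ca[[i]]^2), rowSums(ca[[j]]^2), "+") -
                      2 * ca[[i]] %*% t(ca[[j]])))
      if (d < 6) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  sheet[idx] <- match(roots, unique(roots))
  sheet
}

#' Perturb a structure with noise and carbonyl misorientation
#'
#' Applies seeded Gaussian displacement to every atom and/or rotates the
#' carbonyl O of selected residues about their C--CA axis, emulating
#' main-chain models whose carbonyls are not parallel to the helical axis.
#'
#' @param structure a `cv_structure`
#' @param noise_sigma standard deviation of the isotropic displacement (A)
#' @param carbonyl_rotation rotation of the C=O bond about the C--CA axis,
#'   degrees
#' @param carbonyl_residues list of `(stretch, residue indices)` pairs, or a
#'   plain integer vector of residue indices into stretch 1
#' @param seed RNG seed (noise only; carbonyl rotation is deterministic)
#' @return the perturbed `cv_structure`
#' @export
perturb <- function(structure, noise_sigma = 0, carbonyl_rotation = 0,
                    carbonyl_residues = NULL, seed = 1L) {
  if (carbonyl_rotation != 0 && !is.null(carbonyl_residues)) {
    if (is.numeric(carbonyl_residues)) {
      carbonyl_residues <- list(list(stretch = 1L, residues = carbonyl_residues))
    }
    for (cr in carbonyl_residues) {
      s <- cr$stretch
      st <- structure$stretches[[s]]
      for (i in cr$residues) {
        axis <- st$xyz$C[i, ] - st$xyz$CA[i, ]
        R <- rotation_about_axis(axis, carbonyl_rotation)
        st$xyz$O[i, ] <- st$xyz$C[i, ] + as.vector(R %*% (st$xyz$O[i, ] - st$xyz$C[i, ]))
      }
      structure$stretches[[s]] <- st
    }
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    for (s in seq_along(structure$stretches)) {
      st <- structure$stretches[[s]]
      n <- length(st$resno)
      # Smooth, low-frequency displacement field plus a small independent
      # jitter. Real imperfect models deform smoothly (restrained bond
      # geometry stays near-ideal), so adjacent residues must move almost
      # together: two random harmonics with wavelengths of 20-40 residues
      # keep the peptide C-N distances inside the bond test while the
      # per-residue displacement has the requested sigma per component.
      field <- matrix(0, n, 3)
      for (h in 1:2) {
        lam <- stats::runif(1, 20, 40)
        for (cmp in 1:3) {
          a <- stats::rnorm(1)
          ph <- stats::runif(1, 0, 2 * pi)
          field[, cmp] <- field[, cmp] + a * sin(2 * pi * seq_len(n) / lam + ph)
        }
      }
      field <- field * noise_sigma / stats::sd(as.vector(field))
      if (n > 1) {
        # clamp the field gradient so the C-N peptide distance always stays
        # inside the connectivity test, whatever the draw
        grad <- max(sqrt(rowSums((field[-1, , drop = FALSE] -
                                    field[-n, , drop = FALSE])^2)))
        if (grad > 0.12) field <- field * 0.12 / grad
      }
      jitter_sd <- min(noise_sigma * 0.1, 0.03)
      for (nm in names(st$xyz)) {
        st$xyz[[nm]] <- st$xyz[[nm]] + field +
          matrix(stats::rnorm(3 * n, sd = jitter_sd), n, 3)
      }
      # repair any peptide bond the tail of the draw pushed out of range:
      # translate the downstream residues along the bond direction
      if (n > 1) for (i in seq_len(n - 1L)) {
        v <- st$xyz$N[i + 1L, ] - st$xyz$C[i, ]
        d <- sqrt(sum(v * v))
        if (d < 1.15 || d > 1.75) {
          shift <- (1.329 - d) * v / d
          idx <- (i + 1L):n
          for (nm in names(st$xyz)) {
            st$xyz[[nm]][idx, ] <- sweep(st$xyz[[nm]][idx, , drop = FALSE],
                                         2, shift, "+")
          }
        }
      }
      structure$stretches[[s]] <- st
    }
  }
  structure
}

#' Random composite fixture (for property tests)
#'
#' Draws 2-4 elements of random type and length, placed apart so that
#' fragments are geometrically distinct, with optional noise.
#'
#' @param seed RNG seed
#' @param noise_sigma coordinate noise in Angstrom
#' @param max_elements maximum number of elements
#' @return as [assemble_fold()]
#' @export
random_fixture <- function(seed = 1L, noise_sigma = 0.15, max_elements = 4L) {
  set.seed(seed)
  n_el <- sample(2:max_elements, 1)
  els <- lapply(seq_len(n_el), function(i) {
    type <- sample(c("ah", "bs", "coil"), 1, prob = c(0.4, 0.4, 0.2))
    len <- sample(5:12, 1)
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 4) + c(0, 14 * (i - 1), 0)
    element(type, len, R = R, t = t)
  })
  assemble_fold(els, noise_sigma = noise_sigma, seed = seed + 1000L)
}
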