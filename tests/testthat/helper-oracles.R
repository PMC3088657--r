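# Independent oracles used to cross-check the package's own implementations.
# Each is written from first principles and shares no code with R/.

# Horn's closed-form quaternion solution to the paired-point rigid fit:
# returns the minimal RMSD mapping b onto a.
horn_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  m <- crossprod(bc, ac)   # sum over points of b_i a_i^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,      -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  ev <- eigen(n4, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- bc %*% t(rot)
  sqrt(mean(rowSums((ac - fitted)^2)))
}

# quadratic-space Needleman-Wunsch global alignment score with affine gaps
# (open + extend per added gap column), BLOSUM62
nw_score <- function(sa, sb, gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e9
  mm <- matrix(neg, n + 1, m + 1)   # ends in a match column
  gx <- matrix(neg, n + 1, m + 1)   # gap in b (a aligned to '-')
  gy <- matrix(neg, n + 1, m + 1)   # gap in a
  mm[1, 1] <- 0
  for (i in seq_len(n)) gx[i + 1, 1] <- -gap_open - gap_extend * i
  for (j in seq_len(m)) gy[1, j + 1] <- -gap_open - gap_extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[a[i], b[j]]
      mm[i + 1, j + 1] <- max(mm[i, j], gx[i, j], gy[i, j]) + s
      gx[i + 1, j + 1] <- max(mm[i, j + 1] - gap_open - gap_extend,
                              gx[i, j + 1] - gap_extend)
      gy[i + 1, j + 1] <- max(mm[i + 1, j] - gap_open - gap_extend,
                              gy[i + 1, j] - gap_extend)
    }
  }
  max(mm[n + 1, m + 1], gx[n + 1, m + 1], gy[n + 1, m + 1])
}

# analytic overlap (lens) volume of two spheres at centre distance d
lens_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * d)
}

# plain-R Shrake-Rupley at arbitrary resolution (golden-spiral points),
# independent of the compiled kernel
sasa_r <- function(atoms, context = NULL, probe = 1.4, n_points = 960) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  r <- ligtrans::vdw_radius(atoms$element)
  if (!is.null(context) && nrow(context) > 0) {
    xyz <- rbind(xyz, cbind(context$x, context$y, context$z))
    r <- c(r, ligtrans::vdw_radius(context$element))
  }
  k <- seq_len(n_points) - 1
  zs <- 1 - 2 * (k + 0.5) / n_points
  th <- pi * (3 - sqrt(5)) * k
  rad <- sqrt(pmax(0, 1 - zs^2))
  sphere <- cbind(rad * cos(th), rad * sin(th), zs)
  n_q <- nrow(atoms)
  out <- numeric(n_q)
  for (i in seq_len(n_q)) {
    ri <- r[i] + probe
    pts <- sweep(sphere * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      rj <- r[j] + probe
      dj <- sqrt(sum((xyz[j, ] - xyz[i, ])^2))
      if (dj >= ri + rj) next
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 >= rj^2
      if (!any(free)) break
    }
    out[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  out
}

# brute-force interaction counts straight from the pairwise distance matrix
brute_counts <- function(prot_atoms, lig, cfg = scoring_config()) {
  pa <- prot_atoms[!toupper(prot_atoms$element) %in% c("H", "D"), ]
  la <- lig$atoms
  b <- 0L; hb_partner <- rep(FALSE, nrow(la)); vdw_partner <- rep(FALSE, nrow(la))
  cc <- 0L; dd <- 0L
  deg <- rep(0L, nrow(la))
  if (nrow(lig$bonds) > 0) {
    for (k in seq_len(nrow(lig$bonds))) {
      deg[lig$bonds$from[k]] <- deg[lig$bonds$from[k]] + 1L
      deg[lig$bonds$to[k]] <- deg[lig$bonds$to[k]] + 1L
    }
  }
  lig_don <- lig_acc <- rep(FALSE, nrow(la))
  for (j in seq_len(nrow(la))) {
    e <- toupper(la$element[j])
    if (e == "O") { lig_acc[j] <- TRUE; lig_don[j] <- deg[j] <= 1 }
    if (e == "N") { lig_don[j] <- TRUE; lig_acc[j] <- deg[j] <= 2 }
    if (e == "S") { lig_acc[j] <- TRUE; lig_don[j] <- deg[j] <= 1 }
  }
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((pa$x[i] - la$x[j])^2 + (pa$y[i] - la$y[j])^2 +
                (pa$z[i] - la$z[j])^2)
      if (d <= cfg$contact_cutoff) b <- b + 1L
      ep <- toupper(pa$element[i])
      p_don <- ep %in% c("N", "S"); p_acc <- ep %in% c("O", "S")
      compat <- (p_don && lig_acc[j]) || (p_acc && lig_don[j])
      if (compat && d >= cfg$hbond_min && d <= cfg$hbond_max) {
        cc <- cc + 1L; hb_partner[j] <- TRUE
      }
      rs <- ligtrans::vdw_radius(pa$element[i]) + ligtrans::vdw_radius(la$element[j])
      if (d <= rs + cfg$vdw_outer && d > rs - cfg$vdw_inner) {
        dd <- dd + 1L; vdw_partner[j] <- TRUE
      }
    }
  }
  list(b = b, c = cc, d = dd,
       e = sum((lig_don | lig_acc) & !hb_partner),
       f = sum(toupper(la$element) == "C" & !vdw_partner))
}

# a tiny hand-built complex: a few protein atoms at controlled distances
# from a template ligand
protein_from_xyz <- function(xyz, elements, seq_letters = NULL) {
  n <- nrow(xyz)
  if (is.null(seq_letters)) seq_letters <- paste(rep("A", n), collapse = "")
  tibble::tibble(
    eleno = seq_len(n), name = ifelse(toupper(elements) == "C", "CA",
                                      toupper(elements)),
    element = toupper(elements),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = "A", resno = seq_len(n), insert = "",
    resid = bio3d::aa123(strsplit(seq_letters, "")[[1]]),
    hetero = FALSE, occ = 1
  )
}

make_chain <- function(xyz, elements, seq_letters = NULL) {
  n <- nrow(xyz)
  if (is.null(seq_letters)) seq_letters <- paste(rep("A", n), collapse = "")
  protein_chain("A", protein_from_xyz(xyz, elements, seq_letters), seq_letters)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
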