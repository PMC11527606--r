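#' @section Collective dynamics:
#' Least-squares rigid superposition (Kabsch, via SVD) underlies the
#' RMSD/RMSF traces, the combined PCA of two concatenated ensembles, and
#' the dynamic cross-correlation matrix (DCCM) of C-alpha displacement
#' vectors. Torsion summaries use circular statistics throughout —
#' arithmetic means of angles near +/-180 degrees are meaningless.
#' @name poregate-collective
NULL

#' Optimal rigid superposition of two coordinate sets
#'
#' Returns the rotation (determinant +1) and translation minimising the
#' RMSD of the selected atoms, mobile onto reference.
#'
#' @param mobile,reference n x 3 coordinate matrices (same n).
#' @param selection optional `pg_selection` (or 0-based indices)
#'   restricting the fit.
#' @return a `pg_superposition`: `rotation` (3x3), `translation`
#'   (length 3; `y = x %*% t(R) + t`), `rmsd`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  idx <- if (is.null(selection)) seq_len(nrow(mobile)) else as_sel_rows(selection)
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  if (nrow(P) < 3L) stop("superposition needs at least 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2L] < 1e-10)
    stop("superposition selection is collinear or degenerate")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cq - R %*% cp)
  fitted <- sweep(tcrossprod(P, R), 2L, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd),
            class = "pg_superposition")
}

apply_superposition <- function(xyz, sup) {
  sweep(tcrossprod(xyz, sup$rotation), 2L, sup$translation, "+")
}

#' Per-frame RMSD trace against a reference frame
#'
#' @param traj a `pg_trajectory`.
#' @param selection atoms entering fit and RMSD (default all).
#' @param reference_frame 0-based reference frame index.
#' @param window optional [frame_window()].
#' @param fit superpose each frame before measuring (default TRUE).
#' @return data frame `frame`, `time_ns`, `rmsd_A`.
#' @export
rmsd_trace <- function(traj, selection = NULL, reference_frame = 0L,
                       window = NULL, fit = TRUE) {
  frames <- window_frames(traj, window)
  idx <- if (is.null(selection)) seq_len(traj$topology$n_atoms)
         else as_sel_rows(selection)
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  vals <- vapply(frames, function(f) {
    x <- frame_coords(traj, f)[idx, , drop = FALSE]
    if (fit) superpose(x, ref)$rmsd
    else sqrt(mean(rowSums((x - ref)^2)))
  }, 0)
  data.frame(frame = frames, time_ns = traj$frame_times[frames + 1L],
             rmsd_A = vals)
}

# Superpose all window frames onto their (iterated) mean; returns the
# stacked fitted coordinates (n_sel x 3 x n_frames) and the mean.
# Batched Kabsch: the 3x3 cross-covariances of all frames are built with
# vectorised column sums, only the 3x3 SVD runs per frame.
fit_to_mean <- function(traj, idx, frames, fit = TRUE, iterations = 2L) {
  n <- length(idx)
  nf <- length(frames)
  X <- traj$coords[idx, , frames + 1L, drop = FALSE]
  dim(X) <- c(n, 3L, nf)
  if (!fit) {
    mean_xyz <- apply(X, c(1L, 2L), mean)
    return(list(coords = X, mean = mean_xyz))
  }
  mean_xyz <- X[, , 1L]
  for (it in seq_len(iterations)) {
    cq <- colMeans(mean_xyz)
    Qc <- sweep(mean_xyz, 2L, cq)
    cm <- apply(X, c(2L, 3L), mean)              # 3 x nf frame centroids
    Xc <- X - array(rep(cm, each = n), dim = c(n, 3L, nf))
    H <- array(0, dim = c(3L, 3L, nf))
    for (a in 1:3) for (b in 1:3) {
      M <- Xc[, a, ]
      if (is.null(dim(M))) M <- matrix(M, nrow = n)
      H[a, b, ] <- colSums(M * Qc[, b])
    }
    for (f in seq_len(nf)) {
      sv <- svd(H[, , f])
      d <- sign(det(tcrossprod(sv$v, sv$u)))
      R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
      X[, , f] <- sweep(tcrossprod(Xc[, , f], R), 2L, cq, "+")
    }
    mean_xyz <- apply(X, c(1L, 2L), mean)
  }
  list(coords = X, mean = mean_xyz)
}

#' Per-residue RMSF profile
#'
#' Frames are superposed onto the window-mean structure (iterated
#' twice); rmsf_i = sqrt(<|r_i - <r_i>|^2>) per selected atom, averaged
#' per residue.
#'
#' @param traj a `pg_trajectory`.
#' @param selection atoms considered (typically CA); default all
#'   protein atoms.
#' @param window optional [frame_window()].
#' @param fit superpose before measuring (disable for planted-motion
#'   closed-form checks).
#' @return data frame `chain`, `resid`, `resname`, `rmsf_A`.
#' @export
rmsf_profile <- function(traj, selection = NULL, window = NULL, fit = TRUE) {
  frames <- window_frames(traj, window)
  topo <- traj$topology
  idx <- if (is.null(selection))
    which(!topo$atoms$is_ion & !topo$atoms$is_ligand)
  else as_sel_rows(selection)
  ft <- fit_to_mean(traj, idx, frames, fit = fit)
  dev2 <- sweep(ft$coords, c(1L, 2L), ft$mean)^2
  per_atom <- sqrt(apply(dev2, 1L, mean) * 3)  # mean over frames of |dr|^2
  a <- topo$atoms[idx, ]
  key <- residue_key(a)
  agg <- tapply(per_atom, key, mean)
  first <- match(names(agg), key)
  out <- data.frame(chain = a$chain[first], resid = a$resid[first],
                    resname = a$resname[first],
                    rmsf_A = as.numeric(agg), stringsAsFactors = FALSE)
  out[order(out$chain, out$resid), ]
}

#' Combined PCA over two concatenated trajectories
#'
#' Frames of both windows are superposed onto the combined mean
#' (mean/superpose iterated twice), the 3N covariance of the selected
#' coordinates is eigen-decomposed, and per-frame projections are
#' labelled by source system. Selections must resolve to identical
#' residue lists in both systems.
#'
#' @param traj_a,traj_b `pg_trajectory` of the two systems.
#' @param sel_a,sel_b matching selections (e.g. all CA).
#' @param window_a,window_b optional [frame_window()]s.
#' @param labels length-2 system labels for the projections.
#' @return a `pg_pca`: `eigenvalues` (descending, A^2), `eigenvectors`
#'   (3N x 3N, orthonormal columns), `mean` (n x 3), `projections`
#'   (data frame frame/system/EV columns), `total_variance`, and
#'   `ensemble` — the superposed flattened coordinates (frames x 3N,
#'   xyz interleaved per atom) for independent variance checks.
#' @export
combined_pca <- function(traj_a, traj_b, sel_a, sel_b,
                         window_a = NULL, window_b = NULL,
                         labels = c("apo", "holo")) {
  idx_a <- as_sel_rows(sel_a); idx_b <- as_sel_rows(sel_b)
  ra <- traj_a$topology$atoms[idx_a, c("chain", "resid", "name")]
  rb <- traj_b$topology$atoms[idx_b, c("chain", "resid", "name")]
  if (!identical(ra, rb)) {
    miss <- unique(c(
      setdiff(paste(ra$chain, ra$resid), paste(rb$chain, rb$resid)),
      setdiff(paste(rb$chain, rb$resid), paste(ra$chain, ra$resid))))
    stop("selections do not match across systems; unmatched residues: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  }
  fa <- window_frames(traj_a, window_a)
  fb <- window_frames(traj_b, window_b)
  n <- length(idx_a)
  Xa <- traj_a$coords[idx_a, , fa + 1L, drop = FALSE]
  Xb <- traj_b$coords[idx_b, , fb + 1L, drop = FALSE]
  X <- array(c(Xa, Xb), dim = c(n, 3L, length(fa) + length(fb)))
  mean_xyz <- X[, , 1L]
  for (it in 1:2) {
    for (f in seq_len(dim(X)[3L])) {
      sup <- superpose(X[, , f], mean_xyz)
      X[, , f] <- apply_superposition(X[, , f], sup)
    }
    mean_xyz <- apply(X, c(1L, 2L), mean)
  }
  flat <- t(apply(X, 3L, function(m) as.numeric(t(m))))  # frames x 3N (xyzxyz...)
  mu <- colMeans(flat)
  D <- sweep(flat, 2L, mu)
  C <- crossprod(D) / nrow(D)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  proj <- D %*% eig$vectors
  projections <- data.frame(
    frame = c(fa, fb),
    system = rep(labels, c(length(fa), length(fb))),
    stringsAsFactors = FALSE)
  for (k in seq_len(min(10L, ncol(proj))))
    projections[[paste0("EV", k)]] <- proj[, k]
  structure(list(eigenvalues = vals, eigenvectors = eig$vectors,
                 mean = mean_xyz, atom_rows = idx_a,
                 projections = projections,
                 total_variance = sum(diag(C)),
                 ensemble = flat,
                 labels = labels),
            class = "pg_pca")
}

#' Export interpolated structures along a principal component
#'
#' Writes a multi-model PDB morph spanning mean +/- `n_sd` SD of the
#' projection along the chosen eigenvector, in `steps` interpolation
#' steps (default six frames, the conventional red-to-blue rendering).
#'
#' @param pca a `pg_pca`.
#' @param topology topology the selection rows refer to.
#' @param path output PDB path.
#' @param ev eigenvector index (1-based).
#' @param steps number of interpolated structures.
#' @param n_sd span in projection standard deviations.
#' @export
write_pca_morph <- function(pca, topology, path, ev = 1L, steps = 6L,
                            n_sd = 2) {
  sdv <- sqrt(pca$eigenvalues[ev])
  amps <- seq(-n_sd * sdv, n_sd * sdv, length.out = steps)
  vec <- pca$eigenvectors[, ev]
  n <- nrow(pca$mean)
  a <- topology$atoms[pca$atom_rows, ]
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(amps)) {
    xyz <- pca$mean + matrix(vec * amps[i], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_pdb_atom_line(seq_len(n), a$name, a$resname, a$chain,
                                    a$resid, xyz[, 1L], xyz[, 2L], xyz[, 3L],
                                    a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Dynamic cross-correlation matrix of C-alpha displacements
#'
#' Frames are superposed onto the window mean; for residues i, j the
#' entry is `c_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with
#' `dr_i(t) = r_i(t) - <r_i>` the CA displacement vector. Residues with
#' zero variance yield 0 with a warning.
#'
#' @param traj a `pg_trajectory`.
#' @param selection residue-granular selection; the CA atom of each
#'   selected residue is used.
#' @param window optional [frame_window()].
#' @param fit superpose before measuring.
#' @return a `pg_correlation_matrix`: `residues` data frame and
#'   `matrix` (symmetric, unit diagonal).
#' @export
correlation_matrix <- function(traj, selection = NULL, window = NULL,
                               fit = TRUE) {
  frames <- window_frames(traj, window)
  if (length(frames) < 2L) stop("correlation needs at least 2 frames")
  topo <- traj$topology
  rows <- if (is.null(selection))
    which(!topo$atoms$is_ion & !topo$atoms$is_ligand)
  else as_sel_rows(selection)
  ca_rows <- rows[topo$atoms$name[rows] == "CA"]
  if (length(ca_rows) < 2L) stop("need at least 2 residues with CA atoms")
  ft <- fit_to_mean(traj, ca_rows, frames, fit = fit)
  dev <- sweep(ft$coords, c(1L, 2L), ft$mean)   # n x 3 x frames
  n <- length(ca_rows)
  # inner products <dr_i . dr_j>: sum over axes of per-axis covariance
  G <- matrix(0, n, n)
  for (ax in 1:3) {
    M <- dev[, ax, ]
    if (is.null(dim(M))) M <- matrix(M, nrow = n)
    G <- G + tcrossprod(M)
  }
  G <- G / length(frames)
  v <- diag(G)
  zero <- v < 1e-12
  if (any(zero))
    warning(sum(zero), " residue(s) with zero variance; correlations set to 0")
  denom <- sqrt(pmax(v, 1e-12))
  C <- G / tcrossprod(denom)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- ifelse(zero, 0, 1)
  a <- topo$atoms[ca_rows, ]
  residues <- data.frame(chain = a$chain, resid = a$resid,
                         resname = a$resname, stringsAsFactors = FALSE)
  dimnames(C) <- list(paste0(residues$chain, ":", residues$resid),
                      paste0(residues$chain, ":", residues$resid))
  structure(list(residues = residues, matrix = C),
            class = "pg_correlation_matrix")
}

#' Difference of residue-pair correlation coefficients
#'
#' Delta = holo - apo per pair, the convention in which a positive
#' correlation present only in the apo system yields a negative
#' difference. Accepts either two `pg_correlation_matrix` objects with
#' matching residue lists, or (for printed worked examples) plain
#' numeric coefficient vectors via `pairs`.
#'
#' @param apo,holo `pg_correlation_matrix` objects, or `NULL` when
#'   `pairs` already carries coefficients.
#' @param pairs optional data frame; either columns `res_a`, `res_b`
#'   (labels "chain:resid" to extract from the matrices) or columns
#'   `pair`, `c_apo`, `c_holo` for direct differencing.
#' @return data frame `pair`, `c_apo`, `c_holo`, `delta`.
#' @export
correlation_difference <- function(apo = NULL, holo = NULL, pairs = NULL) {
  if (!is.null(pairs) && all(c("c_apo", "c_holo") %in% names(pairs))) {
    out <- data.frame(pair = pairs$pair, c_apo = pairs$c_apo,
                      c_holo = pairs$c_holo,
                      delta = pairs$c_holo - pairs$c_apo,
                      stringsAsFactors = FALSE)
    return(out)
  }
  stopifnot(inherits(apo, "pg_correlation_matrix"),
            inherits(holo, "pg_correlation_matrix"))
  if (!identical(apo$residues, holo$residues))
    stop("correlation matrices cover different residue lists")
  if (is.null(pairs)) {
    labs <- rownames(apo$matrix)
    idx <- which(upper.tri(apo$matrix), arr.ind = TRUE)
    pairs <- data.frame(res_a = labs[idx[, 1L]], res_b = labs[idx[, 2L]],
                        stringsAsFactors = FALSE)
  }
  ca <- mapply(function(i, j) apo$matrix[i, j], pairs$res_a, pairs$res_b)
  ch <- mapply(function(i, j) holo$matrix[i, j], pairs$res_a, pairs$res_b)
  data.frame(pair = paste(pairs$res_a, pairs$res_b, sep = "-"),
             c_apo = as.numeric(ca), c_holo = as.numeric(ch),
             delta = as.numeric(ch) - as.numeric(ca),
             stringsAsFactors = FALSE)
}
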