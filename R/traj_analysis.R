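#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of `Y` onto `X` over a proper rotation
#' (det = +1) and translation, via singular value decomposition of the
#' weighted covariance matrix.
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3), matching atom order.
#' @param weights Optional per-atom weights (default uniform).
#' @return List with `rotation` (3 x 3), `translation` (length 3, to
#'   be applied after rotation), `rmsd` (Angstrom) and `Yfit` (the
#'   transformed Y).
#' @export
superpose <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("coordinate sets differ in size")
  n <- nrow(X)
  if (n < 3) stop("underdetermined: need at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cx <- colSums(X * w)
  cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  H <- t(Yc * w) %*% Xc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Yrot <- Yc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((Yrot - Xc)^2)))
  Yfit <- sweep(Yrot, 2, cx, `+`)
  list(rotation = R, translation = as.numeric(cx - (cy %*% t(R))),
       rmsd = rmsd, Yfit = Yfit)
}

#' Pairwise RMSD after optimal superposition
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(X, Y, weights = NULL) superpose(X, Y, weights)$rmsd

# Resolve a selection into atom indices. NULL picks the per-residue
# representative: CA atoms when present, otherwise every atom.
.resolve_selection <- function(traj, system = NULL, selection = NULL) {
  n_atoms <- dim(traj$coords)[2]
  if (!is.null(selection)) return(selection)
  if (!is.null(system) && "CA" %in% system$atoms$name) {
    return(which(system$atoms$name == "CA"))
  }
  seq_len(n_atoms)
}

# Iteratively superpose every frame onto the mean structure.
.fit_frames <- function(coords, rounds = 2) {
  nf <- dim(coords)[1]
  ref <- coords[1, , , drop = TRUE]
  for (r in seq_len(rounds)) {
    for (f in seq_len(nf)) {
      coords[f, , ] <- superpose(ref, coords[f, , , drop = TRUE])$Yfit
    }
    ref <- apply(coords, c(2, 3), mean)
  }
  coords
}

#' Per-residue root mean square fluctuations
#'
#' After (optionally) superposing every frame onto the iteratively
#' refined mean structure, computes
#' \eqn{RMSF_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}}
#' for each selected atom.
#'
#' @param traj A `dmd_trajectory` with >= 2 frames.
#' @param system Optional [molecular_system()] used to pick the default
#'   selection (CA atoms when present).
#' @param selection Optional atom indices.
#' @param fit Superpose frames before measuring (default `TRUE`)?
#' @param equilibration Fraction of frames discarded from the front.
#' @return Tibble with columns `atom` (index) and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, system = NULL, selection = NULL, fit = TRUE,
                 equilibration = 0) {
  sel <- .resolve_selection(traj, system, selection)
  nf <- n_frames(traj)
  if (nf < 2) {
    warning("single frame: zero variance, RMSF is 0 everywhere")
    return(tibble::tibble(atom = sel, rmsf = 0))
  }
  keep <- (floor(equilibration * nf) + 1):nf
  coords <- traj$coords[keep, sel, , drop = FALSE]
  if (fit) coords <- .fit_frames(coords)
  mean_pos <- apply(coords, c(2, 3), mean)
  dev2 <- sweep(coords, c(2, 3), mean_pos)^2
  msf <- apply(dev2, 2, sum) / dim(coords)[1]
  tibble::tibble(atom = sel, rmsf = sqrt(msf))
}

#' Correlated-motion map of residue pairs
#'
#' The dynamic cross-correlation matrix: after superposition, the
#' normalized isotropic covariance of displacement vectors,
#' \eqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' \sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}},
#' where \eqn{\Delta r} is the deviation from the mean position. +1
#' marks fully correlated motion, -1 fully anti-correlated.
#'
#' @inheritParams rmsf
#' @return Object of class `correlation_map`: `matrix` (values in
#'   [-1, 1], unit diagonal), `labels`, and `flagged` (indices of
#'   zero-variance residues whose rows were zeroed).
#' @export
correlation_map <- function(traj, system = NULL, selection = NULL,
                            fit = TRUE, equilibration = 0) {
  sel <- .resolve_selection(traj, system, selection)
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  keep <- (floor(equilibration * nf) + 1):nf
  coords <- traj$coords[keep, sel, , drop = FALSE]
  if (fit) coords <- .fit_frames(coords)
  mean_pos <- apply(coords, c(2, 3), mean)
  dev <- sweep(coords, c(2, 3), mean_pos)
  nsel <- length(sel)
  nfk <- dim(coords)[1]
  # covariance of displacement vectors via flattened dot products
  flat <- matrix(aperm(dev, c(2, 3, 1)), nrow = nsel)  # nsel x (3*nf)
  cov_ij <- flat %*% t(flat) / nfk
  v <- diag(cov_ij)
  flagged <- which(v <= 1e-14)
  denom <- sqrt(outer(v, v))
  C <- cov_ij / denom
  if (length(flagged)) {
    C[flagged, ] <- 0
    C[, flagged] <- 0
  }
  diag(C) <- 1
  C[C > 1] <- 1
  C[C < -1] <- -1
  labels <- if (!is.null(system)) {
    paste0(system$atoms$chain[sel], system$atoms$resno[sel])
  } else as.character(sel)
  dimnames(C) <- list(labels, labels)
  structure(list(matrix = C, labels = labels, flagged = flagged),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("<correlation_map> ", nrow(x$matrix), " residues",
      if (length(x$flagged)) paste0(", ", length(x$flagged),
                                    " zero-variance flagged") else "",
      "\n", sep = "")
  invisible(x)
}

#' Difference between two correlation maps
#'
#' Element-wise `A - B` over identically labelled residues: positive
#' values mark increased correlated motion in `A`, negative decreased.
#'
#' @param A,B `correlation_map` objects with identical residue labels.
#' @return Signed matrix with zero diagonal, values in [-2, 2].
#' @export
difference_map <- function(A, B) {
  stopifnot(inherits(A, "correlation_map"), inherits(B, "correlation_map"))
  if (!identical(A$labels, B$labels)) {
    bad <- union(setdiff(A$labels, B$labels), setdiff(B$labels, A$labels))
    stop("residue labels do not match: ", paste(bad, collapse = ", "))
  }
  D <- A$matrix - B$matrix
  diag(D) <- 0
  D
}

#' Tidy a correlation map (or difference matrix) into long format
#'
#' @param x A `correlation_map` or a labelled square matrix.
#' @param ... Unused.
#' @return Tibble with columns `res_i`, `res_j`, `value`.
#' @export
tidy.correlation_map <- function(x, ...) {
  m <- if (inherits(x, "correlation_map")) x$matrix else x
  tibble::tibble(res_i = rep(rownames(m), times = ncol(m)),
                 res_j = rep(colnames(m), each = nrow(m)),
                 value = as.numeric(m))
}
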