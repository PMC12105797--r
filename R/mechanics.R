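# Quasi-static linear elasticity on the voxelized brain domain.
#
# The tumour exerts a body force proportional to the gradient of total
# normalized density; the resulting displacement field obeys the isotropic
# equilibrium equation with tissue-specific shear moduli and a slip boundary
# condition on the brain surface (no normal displacement, tangential free).
# Hooke's law gives the stress tensor and the von Mises stress, which in
# turn damps tumour cell diffusion exponentially.

# Central-difference matrix along direction d on mask voxels.
# ghost: value assumed at an out-of-mask neighbour, expressed relative to
# the centre voxel: "anti" (= -u_i, normal component of a slip boundary),
# "sym" (= u_i, tangential component / zero normal derivative) or
# "zero" (= 0, fields that vanish outside the brain).
.diff_matrix <- function(grid, d, ghost = c("zero", "sym", "anti")) {
  ghost <- match.arg(ghost)
  nb <- .neighbour_table(grid)
  n <- grid$n_inside
  h2 <- 2 * grid$spacing[d]
  plus <- nb[2 * d, ]; minus <- nb[2 * d - 1, ]
  i <- integer(0); j <- integer(0); v <- numeric(0)
  m <- seq_len(n)
  ok <- plus > 0
  i <- c(i, m[ok]); j <- c(j, plus[ok]); v <- c(v, rep(1 / h2, sum(ok)))
  ok <- minus > 0
  i <- c(i, m[ok]); j <- c(j, minus[ok]); v <- c(v, rep(-1 / h2, sum(ok)))
  if (ghost != "zero") {
    s <- if (ghost == "sym") 1 else -1
    ok <- plus == 0
    i <- c(i, m[ok]); j <- c(j, m[ok]); v <- c(v, rep(s / h2, sum(ok)))
    ok <- minus == 0
    i <- c(i, m[ok]); j <- c(j, m[ok]); v <- c(v, rep(-s / h2, sum(ok)))
  }
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

# Flux-form variable-coefficient Laplacian div(G grad u_e) for displacement
# component e, with slip ghost rules (antisymmetric across faces normal to
# e, zero-flux across tangential faces).
.lap_matrix <- function(grid, e, G) {
  nb <- .neighbour_table(grid)
  n <- grid$n_inside
  i <- integer(0); j <- integer(0); v <- numeric(0)
  m <- seq_len(n)
  for (d in 1:3) {
    h2 <- grid$spacing[d]^2
    for (side in 1:2) {
      nbr <- nb[2 * (d - 1) + side, ]
      ok <- nbr > 0
      Gf <- (G[m[ok]] + G[nbr[ok]]) / 2
      i <- c(i, m[ok], m[ok]); j <- c(j, nbr[ok], m[ok])
      v <- c(v, Gf / h2, -Gf / h2)
      if (d == e) {  # normal component: u = 0 on the boundary face
        out <- !ok
        i <- c(i, m[out]); j <- c(j, m[out]); v <- c(v, -2 * G[m[out]] / h2)
      }
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

#' Assemble and factorize the mechanical equilibrium operator
#'
#' Builds the sparse finite-difference operator of the linear-elastic
#' equilibrium equation on the brain mask, together with the gradient
#' operators needed for the body-force right-hand side and the strain
#' post-processing, and precomputes a sparse LU factorization. The operator
#' depends only on the grid and the elastic constants, so it is built once
#' per anatomy and cached.
#'
#' @param grid A \code{tumour_grid}.
#' @param constants \code{model_constants}.
#' @return List with the operator, its factorization and helper matrices.
#' @keywords internal
build_mechanics <- function(grid, constants = model_constants()) {
  key <- "mech"
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  n <- grid$n_inside
  lab <- grid$tissue[grid$brain_mask]
  G <- ifelse(lab == 1L, constants$G_w, constants$G_g)
  Tc <- G / (1 - 2 * constants$nu)

  Danti <- lapply(1:3, function(d) .diff_matrix(grid, d, "anti"))
  Dsym  <- lapply(1:3, function(d) .diff_matrix(grid, d, "sym"))
  Dzero <- lapply(1:3, function(d) .diff_matrix(grid, d, "zero"))

  # divergence of u: derivative of each component along its own direction
  # (normal/antisymmetric ghost); S is n x 3n over (ux, uy, uz)
  S <- do.call(cbind, lapply(1:3, function(e) Danti[[e]]))
  TS <- Matrix::Diagonal(x = Tc) %*% S
  zero_n <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(n, n))
  lap3 <- do.call(rbind, lapply(1:3, function(d) {
    lap <- .lap_matrix(grid, d, G)
    do.call(cbind, lapply(1:3, function(e) if (e == d) lap else zero_n))
  }))
  # grad(T div u) assembled in its symmetric (weak) form -S' T S, so the
  # whole operator is symmetric negative definite and admits a sparse
  # Cholesky factorization
  A <- lap3 - Matrix::t(S) %*% TS
  fac <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(-A), LDL = FALSE, perm = TRUE),
    error = function(e)
      stop("mechanical equilibrium operator is singular: ",
           conditionMessage(e)))

  # strain operators: derivative of component e along d with the ghost rule
  # of component e across direction-d faces
  Dstrain <- lapply(1:3, function(e) lapply(1:3, function(d)
    if (e == d) Danti[[d]] else Dsym[[d]]))

  lambdaL <- 2 * G * constants$nu / (1 - 2 * constants$nu)

  # density -> displacement is linear; precompute the dense solved map so
  # the per-day mechanics refresh inside a simulation reduces to a handful
  # of matrix-vector products. Stress components are precomposed sparse
  # operators u -> sigma_r (Hooke's law folded in).
  B <- do.call(rbind, lapply(1:3, function(d) constants$lambda2 * Dzero[[d]]))
  Umap <- as.matrix(Matrix::solve(fac, B))
  zero_n <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(n, n))
  strain_op <- function(e, d) {  # n x 3n operator u -> eps_ed
    blocks <- rep(list(zero_n), 3)
    blocks[[e]] <- blocks[[e]] + 0.5 * Dstrain[[e]][[d]]
    blocks[[d]] <- blocks[[d]] + 0.5 * Dstrain[[d]][[e]]
    do.call(cbind, blocks)
  }
  eps_ops <- list(strain_op(1, 1), strain_op(2, 2), strain_op(3, 3),
                  strain_op(1, 2), strain_op(1, 3), strain_op(2, 3))
  DG <- Matrix::Diagonal(x = 2 * G)
  DL <- Matrix::Diagonal(x = lambdaL)
  tr_op <- eps_ops[[1]] + eps_ops[[2]] + eps_ops[[3]]
  SIG <- methods::as(do.call(rbind, c(
    lapply(1:3, function(r) DG %*% eps_ops[[r]] + DL %*% tr_op),
    lapply(4:6, function(r) DG %*% eps_ops[[r]]))), "CsparseMatrix")
  Bmat <- methods::as(B, "CsparseMatrix")

  csc_of <- function(M) list(p = M@p, i = M@i, x = M@x)
  Lchol <- methods::as(Matrix::expand(fac)$L, "CsparseMatrix")
  mech <- list(n = n, A = A, fac = fac, G = G, Tc = Tc,
               Dzero = Dzero, Dstrain = Dstrain,
               lambdaL = lambdaL, lambda2 = constants$lambda2,
               Bmat = Bmat, SIG = SIG,
               csc = list(B = csc_of(Bmat), L = csc_of(Lchol),
                          S = csc_of(SIG), perm = fac@perm))
  grid$cache[[key]] <- mech
  mech
}

# Fast von Mises stress from density vector(s) over mask voxels (columns =
# independent density fields), via the cached factorization and the
# precomposed Hooke operator. Equivalent to solve_mechanics() without the
# residual audit and array packing.
.von_mises_fast <- function(mech, dens) {
  n <- mech$n
  s <- as.matrix(mech$SIG %*% -Matrix::solve(mech$fac, mech$Bmat %*% dens))
  dim(s) <- c(n, 6L, ncol(s) %||% 1L)
  out <- sqrt(0.5 * ((s[, 1, ] - s[, 2, ])^2 + (s[, 2, ] - s[, 3, ])^2 +
                       (s[, 3, ] - s[, 1, ])^2) +
                3 * (s[, 4, ]^2 + s[, 5, ]^2 + s[, 6, ]^2))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve tissue mechanics for a given tumour burden
#'
#' Solves the linear-elastic equilibrium equation with body force
#' proportional to the gradient of total normalized tumour density, then
#' evaluates the stress tensor by isotropic Hooke's law and the von Mises
#' stress from its deviatoric part.
#'
#' @param total_density Numeric array (\code{N_E + N_N}), zero outside the
#'   brain mask.
#' @param grid A \code{tumour_grid}.
#' @param constants \code{model_constants}.
#' @return List with \code{displacement} (n x 3 matrix over mask voxels, mm),
#'   \code{stress} (n x 6 matrix: xx, yy, zz, xy, xz, yz, kPa) and
#'   \code{von_mises} (array over the full grid, kPa, zero outside).
#' @examples
#' an <- make_anatomy(1, dims = c(16, 16, 3))
#' ms <- solve_mechanics(an$initial$NE + an$initial$NN, an$grid)
#' max(ms$von_mises)
#' @export
solve_mechanics <- function(total_density, grid, constants = model_constants()) {
  if (!all(is.finite(total_density)))
    stop("non-finite values in total_density")
  if (any(total_density[!grid$brain_mask] != 0))
    stop("total_density must be zero outside the brain mask")
  mech <- build_mechanics(grid, constants)
  dens <- total_density[grid$brain_mask]
  b <- unlist(lapply(1:3, function(d)
    mech$lambda2 * as.numeric(mech$Dzero[[d]] %*% dens)), use.names = FALSE)
  u <- -as.numeric(Matrix::solve(mech$fac, b))  # factor holds -A
  res <- sqrt(sum((as.numeric(mech$A %*% u) - b)^2))
  if (!is.finite(res) || res > 1e-8 * max(1, sqrt(sum(b^2))))
    stop(sprintf("mechanics solve did not converge (residual %.3e)", res))

  n <- mech$n
  uc <- list(u[1:n], u[n + 1:n], u[2 * n + 1:n])
  eps <- matrix(0, n, 6)  # xx, yy, zz, xy, xz, yz
  comp <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (r in 1:6) {
    e <- comp[r, 1]; d <- comp[r, 2]
    eps[, r] <- 0.5 * (as.numeric(mech$Dstrain[[e]][[d]] %*% uc[[e]]) +
                         as.numeric(mech$Dstrain[[d]][[e]] %*% uc[[d]]))
  }
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  sig <- 2 * mech$G * eps
  for (r in 1:3) sig[, r] <- sig[, r] + mech$lambdaL * tr
  vm <- sqrt(0.5 * ((sig[, 1] - sig[, 2])^2 + (sig[, 2] - sig[, 3])^2 +
                      (sig[, 3] - sig[, 1])^2) +
               3 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2))
  vm_field <- array(0, grid$dims)
  vm_field[grid$brain_mask] <- vm
  list(displacement = do.call(cbind, uc), stress = sig, von_mises = vm_field)
}

#' Stress-damped diffusion coefficient
#'
#' Local tumour cell diffusion decreases exponentially with von Mises
#' stress: \code{D = D0 * exp(-lambda1 * sigma_vm)}. With \code{lambda1 = 0}
#' or zero stress the unrestricted coefficient is recovered; as stress grows
#' the coefficient tends to zero.
#'
#' @param D0_field Unrestricted diffusion field (mm^2/day), assigned from
#'   the white/grey coefficients by tissue label.
#' @param von_mises Von Mises stress field (kPa).
#' @param lambda1 Stress-diffusion coupling (1/kPa), non-negative.
#' @return Damped diffusion field, same shape as \code{D0_field}.
#' @export
damp_diffusion <- function(D0_field, von_mises, lambda1) {
  if (lambda1 < 0) stop("lambda1 must be non-negative")
  D0_field * exp(-lambda1 * von_mises)
}
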