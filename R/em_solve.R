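#' Solve the assembled curl-curl system
#'
#' Solves the real 2N x 2N block system
#' `[[A_re, -A_im], [A_im, A_re]] [E_re; E_im] = [b_re; b_im]`
#' (the real/imaginary split of `A_c x = b_c` with `A_c = A_re + j A_im`,
#' `b_c = b_re + j b_im`; the two block rows are exactly the printed pair of
#' real-valued weak equations) by a sparse direct factorization, after
#' eliminating the perfectly conducting edges. The relative residual of the
#' complex system is computed and reported.
#'
#' @param system an `abl_em_system` from [assemble_system()]
#' @param rtol residual tolerance; a larger residual is an error
#' @return object of class `abl_em_solution`: complex edge coefficients
#'   (`coeff`, zero on PEC edges), `residual`, and the system's mesh/edges
#' @export
solve_em <- function(system, rtol = 1e-8) {
  free <- system$free
  Are <- system$Are[free, free, drop = FALSE]
  Aim <- system$Aim[free, free, drop = FALSE]
  b <- system$b[free]
  if (all(Mod(b) == 0)) {
    coeff <- complex(system$n_edges)
    return(structure(list(coeff = coeff, residual = 0,
                          mesh = system$mesh, edges = system$edges,
                          materials = system$materials),
                     class = "abl_em_solution"))
  }
  nf <- length(free)
  # the block system is equivalent to the symmetric indefinite form
  # [[Are, -Aim], [-Aim, -Are]] [x_re; x_im] = [b_re; -b_im], which
  # CHOLMOD's sparse LDL' factors far faster than a general sparse LU; fall
  # back to LU if a zero pivot is hit
  x <- tryCatch({
    As <- Matrix::forceSymmetric(
      Matrix::rbind2(Matrix::cbind2(Are, -Aim), Matrix::cbind2(-Aim, -Are)))
    ch <- Matrix::Cholesky(As, LDL = TRUE, perm = TRUE, super = FALSE)
    xs <- as.numeric(Matrix::solve(ch, c(Re(b), -Im(b))))
    xs
  }, error = function(e) NULL)
  if (is.null(x)) {
    A <- Matrix::rbind2(Matrix::cbind2(Are, -Aim), Matrix::cbind2(Aim, Are))
    x <- tryCatch(
      as.numeric(Matrix::solve(A, c(Re(b), Im(b)), sparse = TRUE)),
      error = function(e) stop("solver error: sparse direct solve failed (",
                               conditionMessage(e),
                               "); is the system constrained (PEC or ",
                               "absorbing boundary) anywhere?"))
  }
  xc <- complex(real = x[seq_len(nf)], imaginary = x[nf + seq_len(nf)])
  r1 <- as.numeric(Are %*% Re(xc) - Aim %*% Im(xc)) - Re(b)
  r2 <- as.numeric(Aim %*% Re(xc) + Are %*% Im(xc)) - Im(b)
  resid <- sqrt(sum(r1^2) + sum(r2^2)) / sqrt(sum(Mod(b)^2))
  if (!is.finite(resid) || resid > rtol)
    stop("solver error: relative residual ", signif(resid, 3),
         " exceeds tolerance ", rtol)
  coeff <- complex(system$n_edges)
  coeff[free] <- xc
  structure(list(coeff = coeff, residual = resid, mesh = system$mesh,
                 edges = system$edges, materials = system$materials),
            class = "abl_em_solution")
}

#' @export
print.abl_em_solution <- function(x, ...) {
  cat("<abl_em_solution> ", length(x$coeff), " edge coefficients, residual ",
      signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

#' Electromagnetic heat source and specific absorption rate
#'
#' Per-element time-averaged |E|^2 (exactly integrated over each element via
#' the element mass matrix), the resistive heat source Qe = sigma |E|^2 / 2
#' (W/m^3) and SAR = Qe / rho (W/kg).
#'
#' @param solution an `abl_em_solution`
#' @param materials an `abl_em_materials` (for sigma per region)
#' @param densities named vector of densities per region (kg/m^3); defaults
#'   to the thermal property table
#' @return list with per-element `E2` (V^2/m^2), `Qe` (W/m^3), `SAR` (W/kg)
#' @export
compute_qe_sar <- function(solution, materials, densities = NULL) {
  mesh <- solution$mesh; edges <- solution$edges
  geom <- tet_geometry(mesh)
  em <- element_matrix_arrays(geom, edges$tet_signs)
  cr <- matrix(Re(solution$coeff)[edges$tet_edges], ncol = 6)
  ci <- matrix(Im(solution$coeff)[edges$tet_edges], ncol = 6)
  E2int <- 0
  for (k in 1:6) for (l in 1:6) {
    col <- (l - 1) * 6 + k
    E2int <- E2int + em$mass[, col] * (cr[, k] * cr[, l] + ci[, k] * ci[, l])
  }
  E2 <- pmax(0, E2int / geom$volume)
  sigma <- region_lookup(materials, mesh, "sigma")
  Qe <- 0.5 * sigma * E2
  if (is.null(densities)) densities <- default_densities()
  rho <- unname(densities[as.character(mesh$region)])
  list(E2 = E2, Qe = Qe, SAR = Qe / rho)
}

default_densities <- function() {
  c(liver = 1030, tumor = 1040, dielectric = 2200, catheter = 2200,
    slot = 1.2)
}

#' Resonant eigenvalues of a closed perfectly conducting cavity
#'
#' Assembles the curl-curl and mass matrices on a mesh whose whole boundary
#' is tagged `pec`, eliminates the boundary edges and solves the dense
#' generalized eigenproblem K x = lambda M x. The physical (nonzero)
#' eigenvalues of the unit cube converge to pi^2 (m^2 + n^2 + p^2) with at
#' least two nonzero indices; the large nullspace (discrete gradients) shows
#' up as near-zero eigenvalues and is returned separately.
#'
#' @param mesh a cavity mesh, all boundary facets tagged `pec`
#' @param zero_tol eigenvalues below `zero_tol * max(lambda)` count as the
#'   gradient nullspace
#' @return list with sorted `nonzero` eigenvalues and `n_zero`
#' @export
cavity_eigenvalues <- function(mesh, zero_tol = 1e-8) {
  edges <- build_edge_structure(mesh)
  geom <- tet_geometry(mesh)
  em <- element_matrix_arrays(geom, edges$tet_signs)
  n <- edges$n_edges
  iidx <- matrix(0L, nrow(mesh$tets), 36); jidx <- iidx
  for (k in 1:6) for (l in 1:6) {
    col <- (l - 1) * 6 + k
    iidx[, col] <- edges$tet_edges[, k]
    jidx[, col] <- edges$tet_edges[, l]
  }
  K <- Matrix::sparseMatrix(i = as.vector(iidx), j = as.vector(jidx),
                            x = as.vector(em$curl), dims = c(n, n))
  M <- Matrix::sparseMatrix(i = as.vector(iidx), j = as.vector(jidx),
                            x = as.vector(em$mass), dims = c(n, n))
  free <- setdiff(seq_len(n), edges$surface_edges$pec)
  Kd <- as.matrix(K[free, free]); Md <- as.matrix(M[free, free])
  lam <- Re(eigen(solve(Md, Kd), only.values = TRUE)$values)
  lam <- sort(pmax(lam, 0))
  thr <- zero_tol * max(lam)
  list(nonzero = lam[lam > thr], n_zero = sum(lam <= thr))
}

#' Dense native-complex reference solve
#'
#' Independent formulation used as a cross-check oracle: forms the complex
#' matrix A_c = A_re + j A_im densely and solves with LAPACK's complex
#' solver. Only sensible for small fixtures.
#'
#' @param system an `abl_em_system`
#' @return complex coefficient vector over all edges
#' @export
solve_em_complex_dense <- function(system) {
  free <- system$free
  Ac <- as.matrix(system$Are[free, free]) +
    1i * as.matrix(system$Aim[free, free])
  xc <- solve(Ac, system$b[free])
  coeff <- complex(system$n_edges)
  coeff[free] <- xc
  coeff
}
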