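#' L1-regularized linear SVM (squared hinge loss)
#'
#' Solves `min_{w,b} ||w||_1 + C * sum_i max(0, 1 - y_i (x_i' w + b))^2` by
#' accelerated proximal gradient (FISTA) with backtracking line search; the
#' intercept is unpenalized. The sparse coefficient vector is the basis for
#' feature ranking.
#'
#' @param x numeric matrix (n x p); columns should be on comparable scales.
#' @param y labels coded -1 / +1 (a 2-level factor or 0/1 vector is recoded).
#' @param C loss weight (> 0); smaller values give sparser solutions.
#' @param max_iter maximum FISTA iterations.
#' @param tol relative objective-change convergence tolerance.
#' @return list with `w` (p coefficients), `b` (intercept), `objective`,
#'   `iterations`, `converged`.
#' @export
l1svm_fit <- function(x, y, C, max_iter = 1000L, tol = 1e-6) {
  x <- as.matrix(x)
  y <- recode_pm1(y)
  if (length(unique(y)) < 2L)
    stop("argument error: labels contain a single class")
  if (C <= 0) stop("C must be > 0")
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n)

  smooth_obj <- function(w, b) {
    h <- pmax(0, 1 - y * (drop(x %*% w) + b))
    C * sum(h^2)
  }
  smooth_grad <- function(w, b) {
    h <- pmax(0, 1 - y * (drop(x %*% w) + b))
    gy <- -2 * C * (h * y)
    list(gw = drop(crossprod(x, gy)), gb = sum(gy))
  }
  objective <- function(w, b) sum(abs(w)) + smooth_obj(w, b)

  w <- numeric(p); b <- 0
  zw <- w; zb <- b
  t_mom <- 1
  # initial step from a crude Lipschitz bound, refined by backtracking
  L <- max(2 * C * (sum(x^2) / n + 1), 1e-8)
  step <- 1 / L
  obj_prev <- objective(w, b)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    step <- step * 1.1  # let the step recover; backtracking re-shrinks it
    g <- smooth_grad(zw, zb)
    f_z <- smooth_obj(zw, zb)
    repeat {
      w_new <- soft_threshold(zw - step * g$gw, step)
      b_new <- zb - step * g$gb
      dw <- w_new - zw; db <- b_new - zb
      f_new <- smooth_obj(w_new, b_new)
      quad <- f_z + sum(g$gw * dw) + g$gb * db +
        (sum(dw^2) + db^2) / (2 * step)
      if (f_new <= quad + 1e-12 * abs(quad)) break
      step <- step / 2
      if (step < 1e-18) break
    }
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    zw <- w_new + ((t_mom - 1) / t_new) * (w_new - w)
    zb <- b_new + ((t_mom - 1) / t_new) * (b_new - b)
    w <- w_new; b <- b_new; t_mom <- t_new
    obj <- sum(abs(w)) + f_new
    if (obj > obj_prev) { # restart momentum on objective increase
      zw <- w; zb <- b; t_mom <- 1
    }
    if (abs(obj_prev - obj) <= tol * max(1, abs(obj_prev))) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  list(w = w, b = b, objective = objective(w, b), iterations = it,
       converged = converged)
}

soft_threshold <- function(v, lambda) sign(v) * pmax(abs(v) - lambda, 0)

recode_pm1 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  u <- sort(unique(y))
  if (length(u) == 1L) return(rep(1, length(y)))
  if (length(u) != 2L) stop("binary labels required, got ", length(u), " classes")
  ifelse(y == u[2L], 1, -1)
}
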