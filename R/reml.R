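# Bivariate sex-stratified REML.
#
# Model: y = (y_m', y_f')' = X beta + g + e with genetic covariance between
# individuals i (sex x) and j (sex z) equal to c_xz * K[i, j], where
# c_mm = sigma2_g_m, c_ff = sigma2_g_f, c_mf = rho * sqrt(sigma2_g_m *
# sigma2_g_f), and diagonal residual covariance with sex-specific
# variances. K is the genomic relationship matrix; the model is the GRM
# form of placing a bivariate normal prior with per-SNP variance
# sigma2_g_x / M on standardized-genotype SNP effects.
#
# The restricted log-likelihood is
#   l_R = -1/2 [ log|V| + log|X' V^-1 X| + y' P y + (n - p) log(2 pi) ],
# with P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1. The (n - p) log(2 pi)
# constant is included, so differences between two evaluations on the same
# data are convention-free.
#
# Fitting is average-information REML: analytic first derivatives
#   d l_R / d theta_k = -1/2 [ tr(P dV_k) - y' P dV_k P y ]
# and the average-information matrix AI_kl = 1/2 y' P dV_k P dV_l P y,
# with Newton-type updates, step-halving, and parameter floors. Variance
# parameters are updated on their natural scale; the cross-sex genetic
# covariance c_mf is a free parameter in the unconstrained model (the
# estimate of rho may therefore exceed 1 in magnitude; V itself is kept
# positive definite by the line search). A derivative-free Nelder-Mead
# restart on log/atanh-transformed parameters is used if AI-REML fails to
# converge.

# ---- fixed-effect designs ----------------------------------------------

# Sex-stratified block design (bivariate model): per-sex intercept and
# per-sex covariate columns. "interaction" (sex-agnostic univariate model):
# intercept, sex main effect, covariates and sex-by-covariate interactions.
# Both span the same column space, so the two models share one mean
# structure.
build_design <- function(cohort, type = c("stratified", "interaction")) {
  type <- match.arg(type)
  n <- length(cohort$ids)
  w <- cohort$covariates
  male <- cohort$sex == "M"
  if (type == "stratified") {
    base <- cbind(`(Intercept)` = 1, w)
    xm <- base * male
    xf <- base * !male
    colnames(xm) <- paste0(colnames(base), ":M")
    colnames(xf) <- paste0(colnames(base), ":F")
    x <- cbind(xm, xf)
  } else {
    sexf <- as.numeric(!male)
    x <- cbind(`(Intercept)` = 1, sexF = sexf)
    if (!is.null(w)) {
      wi <- w * sexf
      colnames(wi) <- paste0(colnames(w), ":sexF")
      x <- cbind(x, w, wi)
    }
  }
  rownames(x) <- cohort$ids
  x
}

# ---- model parametrizations --------------------------------------------

# Each variant maps its free parameter vector theta to the five natural
# parameters nat = (c11, c22, c12, e_m, e_f) with Jacobian dnat/dtheta.
# `clamp` projects an updated theta back into the admissible region: the
# cross-sex covariance (or correlation) is kept within rho_max times the
# PSD bound. Allowing the estimate to float moderately beyond |rho| = 1
# avoids piling probability mass on a boundary under a rho = 1 truth
# (which would make the LRT conservative), while still excluding the
# degenerate region where one genetic variance collapses and the
# cross-covariance runs away.
model_spec <- function(model, rho_max = 1.5) {
  switch(model,
    free = list(
      p = 5L, names = c("sigma2_g_m", "sigma2_g_f", "cov_g",
                        "sigma2_e_m", "sigma2_e_f"),
      lower = function(fl) c(fl, fl, -Inf, fl, fl),
      clamp = function(th) {
        b <- rho_max * sqrt(th[1] * th[2])
        th[3] <- sign(th[3]) * min(abs(th[3]), b)
        th
      },
      map = function(th) th,
      jac = function(th) diag(5),
      init = function(vm, vf) c(vm / 2, vf / 2, 0.5 * sqrt(vm * vf) / 2,
                                vm / 2, vf / 2)
    ),
    rho1 = list(
      p = 4L, names = c("sigma2_g_m", "sigma2_g_f",
                        "sigma2_e_m", "sigma2_e_f"),
      lower = function(fl) rep(fl, 4),
      clamp = identity,
      map = function(th) c(th[1], th[2], sqrt(th[1] * th[2]), th[3], th[4]),
      jac = function(th) {
        j <- matrix(0, 5, 4)
        j[1, 1] <- 1; j[2, 2] <- 1
        j[3, 1] <- 0.5 * sqrt(th[2] / th[1])
        j[3, 2] <- 0.5 * sqrt(th[1] / th[2])
        j[4, 3] <- 1; j[5, 4] <- 1
        j
      },
      init = function(vm, vf) c(vm / 2, vf / 2, vm / 2, vf / 2)
    ),
    equal_h2 = list(
      p = 4L, names = c("sigma2_m", "sigma2_f", "lambda", "rho"),
      lower = function(fl) c(fl, fl, fl, -Inf),
      clamp = function(th) {
        th[4] <- sign(th[4]) * min(abs(th[4]), rho_max)
        th
      },
      map = function(th) c(th[1], th[2], th[4] * sqrt(th[1] * th[2]),
                           th[3] * th[1], th[3] * th[2]),
      jac = function(th) {
        s <- sqrt(th[1] * th[2])
        j <- matrix(0, 5, 4)
        j[1, 1] <- 1; j[2, 2] <- 1
        j[3, 1] <- th[4] * th[2] / (2 * s)
        j[3, 2] <- th[4] * th[1] / (2 * s)
        j[3, 4] <- s
        j[4, 1] <- th[3]; j[4, 3] <- th[1]
        j[5, 2] <- th[3]; j[5, 3] <- th[2]
        j
      },
      init = function(vm, vf) c(vm / 2, vf / 2, 1, 0.5)
    ),
    univariate = list(
      p = 2L, names = c("sigma2_g", "sigma2_e"),
      lower = function(fl) c(fl, fl),
      clamp = identity,
      map = function(th) c(th[1], th[1], th[1], th[2], th[2]),
      jac = function(th) {
        j <- matrix(0, 5, 2)
        j[1:3, 1] <- 1; j[4:5, 2] <- 1
        j
      },
      init = function(vm, vf) {
        v <- (vm + vf) / 2
        c(v / 2, v / 2)
      }
    ),
    stop_config("unknown model variant: ", model)
  )
}

# ---- likelihood evaluation ----------------------------------------------

build_v <- function(nat, K, sex_int) {
  c2 <- matrix(c(nat[1], nat[3], nat[3], nat[2]), 2, 2)
  v <- K * c2[sex_int, sex_int]
  diag(v) <- diag(v) + c(nat[4], nat[5])[sex_int]
  v
}

# Restricted log-likelihood (and optionally analytic score + AI matrix in
# natural-parameter space) at one parameter point. Returns NULL when V is
# not positive definite. Blocks of K are passed pre-extracted for speed.
eval_reml <- function(nat, K, y, X, mi, fi, blocks = NULL, deriv = FALSE) {
  n <- length(y)
  p <- ncol(X)
  if (any(!is.finite(nat))) return(NULL)
  v <- build_v(nat, K, sex_int = {
    s <- integer(n); s[mi] <- 1L; s[fi] <- 2L; s
  })
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdet_v <- 2 * sum(log(diag(ch)))

  if (!deriv) {
    # cheap path: triangular solves only
    a <- backsolve(ch, cbind(X, y), transpose = TRUE)
    ax <- a[, seq_len(p), drop = FALSE]
    ay <- a[, p + 1L]
    xtvx <- crossprod(ax)
    chx <- tryCatch(chol(xtvx), error = function(e) NULL)
    if (is.null(chx)) stop("fixed-effect matrix is rank deficient given V")
    logdet_x <- 2 * sum(log(diag(chx)))
    xtvy <- crossprod(ax, ay)
    beta <- backsolve(chx, backsolve(chx, xtvy, transpose = TRUE))
    ypy <- sum(ay^2) - sum(xtvy * beta)
    ll <- -0.5 * (logdet_v + logdet_x + ypy + (n - p) * log(2 * pi))
    return(list(ll = ll, beta = drop(beta)))
  }

  vinv <- chol2inv(ch)
  t_mat <- vinv %*% X
  xtvx <- crossprod(X, t_mat)
  chx <- tryCatch(chol(xtvx), error = function(e) NULL)
  if (is.null(chx)) stop("fixed-effect matrix is rank deficient given V")
  logdet_x <- 2 * sum(log(diag(chx)))
  q <- chol2inv(chx)
  beta <- drop(q %*% crossprod(t_mat, y))
  r <- y - X %*% beta
  py <- drop(vinv %*% r)
  ypy <- sum(r * py)
  ll <- -0.5 * (logdet_v + logdet_x + ypy + (n - p) * log(2 * pi))

  kmm <- blocks$kmm; kff <- blocks$kff; kmf <- blocks$kmf
  w <- vinv * K
  dvinv <- diag(vinv)
  tr_v <- c(sum(w[mi, mi]), sum(w[fi, fi]), 2 * sum(w[mi, fi]),
            sum(dvinv[mi]), sum(dvinv[fi]))

  tm <- t_mat[mi, , drop = FALSE]
  tf <- t_mat[fi, , drop = FALSE]
  tat <- vector("list", 5L)
  tat[[1]] <- crossprod(tm, kmm %*% tm)
  tat[[2]] <- crossprod(tf, kff %*% tf)
  b <- crossprod(tm, kmf %*% tf)
  tat[[3]] <- b + t(b)
  tat[[4]] <- crossprod(tm)
  tat[[5]] <- crossprod(tf)
  tr_p <- tr_v - vapply(tat, function(a) sum(q * a), numeric(1))

  um <- py[mi]; uf <- py[fi]
  vm <- matrix(0, n, 5L)
  vm[mi, 1] <- kmm %*% um
  vm[fi, 2] <- kff %*% uf
  vm[mi, 3] <- kmf %*% uf
  vm[fi, 3] <- crossprod(kmf, um)
  vm[mi, 4] <- um
  vm[fi, 5] <- uf
  ypvpy <- drop(crossprod(vm, py))
  score <- -0.5 * (tr_p - ypvpy)
  pv <- vinv %*% vm - t_mat %*% (q %*% crossprod(t_mat, vm))
  ai <- 0.5 * crossprod(vm, pv)

  list(ll = ll, beta = beta, py = py, score = score, ai = ai, ypy = ypy)
}

# Haseman-Elston-style moment estimates used as starting values: regress
# phenotype cross-products on GRM entries within and between the sex
# blocks (closed form, O(n^2)). Clamped to a comfortably interior region;
# AI-REML then typically needs only a handful of iterations.
he_init <- function(K, y, X, mi, fi) {
  b <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                error = function(e) NULL)
  if (is.null(b)) return(NULL)
  r <- drop(y - X %*% b)
  rm_ <- r[mi]; rf_ <- r[fi]
  kmm <- K[mi, mi]; kff <- K[fi, fi]; kmf <- K[mi, fi, drop = FALSE]
  cblock <- function(ra, rb, kab, same) {
    if (same) {
      num <- drop(crossprod(ra, kab %*% ra)) - sum(ra^2 * diag(kab))
      den <- sum(kab^2) - sum(diag(kab)^2)
    } else {
      num <- drop(crossprod(ra, kab %*% rb))
      den <- sum(kab^2)
    }
    if (den <= 0) return(NA_real_)
    num / den
  }
  vm <- mean(rm_^2); vf <- mean(rf_^2)
  c11 <- cblock(rm_, rm_, kmm, TRUE)
  c22 <- cblock(rf_, rf_, kff, TRUE)
  c12 <- cblock(rm_, rf_, kmf, FALSE)
  if (anyNA(c(c11, c22, c12))) return(NULL)
  c11 <- min(max(c11, 0.02 * vm), 0.95 * vm)
  c22 <- min(max(c22, 0.02 * vf), 0.95 * vf)
  rho <- c12 / sqrt(c11 * c22)
  rho <- min(max(rho, -0.9), 0.9)
  list(c11 = c11, c22 = c22, c12 = rho * sqrt(c11 * c22),
       e1 = max(vm - c11, 0.05 * vm), e2 = max(vf - c22, 0.05 * vf))
}

# ---- the AI-REML driver -------------------------------------------------

reml_engine <- function(K, y, X, sex_int, model, init = NULL,
                        options = list()) {
  opt <- modifyList(list(max_iter = 200L, tol_obj = 1e-8, tol_par = 1e-6,
                         floor_frac = 1e-8, restarts = 3L, rho_max = 1.5,
                         verbose = FALSE), options)
  spec <- model_spec(model, rho_max = opt$rho_max)
  n <- length(y)
  mi <- which(sex_int == 1L)
  fi <- which(sex_int == 2L)
  assert_that(model == "univariate" || (length(mi) >= 4 && length(fi) >= 4),
              "bivariate fits need at least 4 individuals of each sex")
  blocks <- list(kmm = K[mi, mi, drop = FALSE],
                 kff = K[fi, fi, drop = FALSE],
                 kmf = K[mi, fi, drop = FALSE])
  vy <- var(y)
  vm <- if (length(mi) > 1) var(y[mi]) else vy
  vf <- if (length(fi) > 1) var(y[fi]) else vy
  floor_val <- opt$floor_frac * vy
  lower <- spec$lower(floor_val)
  theta0 <- init
  if (is.null(theta0)) {
    he <- he_init(K, y, X, mi, fi)
    theta0 <- if (is.null(he)) spec$init(vm, vf) else switch(model,
      free = c(he$c11, he$c22, he$c12, he$e1, he$e2),
      rho1 = c(he$c11, he$c22, he$e1, he$e2),
      equal_h2 = c(he$c11, he$c22,
                   max((he$e1 / he$c11 + he$e2 / he$c22) / 2, 1e-3),
                   min(max(he$c12 / sqrt(he$c11 * he$c22), -0.9), 0.9)),
      univariate = c((he$c11 + he$c22) / 2, (he$e1 + he$e2) / 2))
  }
  stopifnot(length(theta0) == spec$p)

  run_once <- function(theta) {
    theta <- spec$clamp(pmax(theta, lower))
    cur <- eval_reml(spec$map(theta), K, y, X, mi, fi, blocks, deriv = TRUE)
    if (is.null(cur)) return(NULL)
    converged <- FALSE
    iter <- 0L
    gnorm <- NA_real_
    while (iter < opt$max_iter) {
      iter <- iter + 1L
      j <- spec$jac(theta)
      g <- drop(crossprod(j, cur$score))
      ai <- crossprod(j, cur$ai %*% j)
      gnorm <- sqrt(sum(g^2))
      delta <- tryCatch(solve(ai, g), error = function(e) NULL)
      if (is.null(delta)) {
        delta <- tryCatch(solve(ai + diag(mean(diag(ai)) * 1e-4, spec$p), g),
                          error = function(e) g / max(1, gnorm))
      }
      step <- 1
      nxt <- NULL
      theta_new <- theta
      repeat {
        theta_try <- spec$clamp(pmax(theta + step * delta, lower))
        nxt <- eval_reml(spec$map(theta_try), K, y, X, mi, fi, blocks,
                         deriv = TRUE)
        if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-10) {
          theta_new <- theta_try
          break
        }
        step <- step / 2
        if (step < 1e-12) { nxt <- NULL; break }
      }
      if (is.null(nxt)) break # stuck: no uphill step found
      dll <- nxt$ll - cur$ll
      dpar <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-8))
      theta <- theta_new
      cur <- nxt
      if (abs(dll) < opt$tol_obj * max(1, abs(cur$ll)) &&
          dpar < opt$tol_par) {
        converged <- TRUE
        break
      }
      if (opt$verbose) {
        message(sprintf("  iter %d: logLr = %.6f", iter, cur$ll))
      }
    }
    list(theta = theta, cur = cur, converged = converged,
         iterations = iter, gradient_norm = gnorm)
  }

  fit <- run_once(theta0)
  restart <- 0L
  # deterministic jittered restarts on non-convergence
  jitters <- list(c(scale = 2), c(scale = 0.5), c(scale = 4))
  while ((is.null(fit) || !fit$converged) && restart < opt$restarts) {
    restart <- restart + 1L
    theta_r <- theta0 * jitters[[restart]][["scale"]]
    cand <- run_once(theta_r)
    if (!is.null(cand) &&
        (is.null(fit) || cand$converged || cand$cur$ll > fit$cur$ll)) {
      fit <- cand
    }
  }
  if (is.null(fit) || !fit$converged || n <= 50) {
    # fallback on non-convergence; at tiny n the REML surface is weakly
    # identified and flat, so always polish with a derivative-free pass
    nm <- nelder_mead_restart(K, y, X, mi, fi, blocks, spec, lower,
                              if (is.null(fit)) theta0 else fit$theta, opt)
    if (!is.null(nm) &&
        (is.null(fit) || nm$cur$ll > fit$cur$ll ||
           (!fit$converged && nm$cur$ll >= fit$cur$ll - 1e-6))) {
      fit <- nm
    }
  }
  if (is.null(fit)) stop("REML fit failed: V not positive definite at any tried parameter value")
  fit$model <- model
  fit$spec <- spec
  fit$lower <- lower
  fit
}

# Derivative-free fallback: Nelder-Mead on log-transformed variance-type
# parameters (signed log for unbounded ones).
nelder_mead_restart <- function(K, y, X, mi, fi, blocks, spec, lower,
                                theta_start, opt) {
  unbounded <- !is.finite(lower)
  to_internal <- function(th) ifelse(unbounded, th, log(pmax(th, lower)))
  from_internal <- function(u) ifelse(unbounded, u, exp(u))
  nll <- function(u) {
    r <- eval_reml(spec$map(spec$clamp(pmax(from_internal(u), lower))),
                   K, y, X, mi, fi, blocks, deriv = FALSE)
    if (is.null(r)) 1e10 else -r$ll
  }
  res <- tryCatch(
    optim(to_internal(pmax(theta_start, lower)), nll,
          method = "Nelder-Mead",
          control = list(maxit = 2000L, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  theta <- spec$clamp(pmax(from_internal(res$par), lower))
  cur <- eval_reml(spec$map(theta), K, y, X, mi, fi, blocks, deriv = TRUE)
  if (is.null(cur)) return(NULL)
  list(theta = theta, cur = cur, converged = res$convergence == 0,
       iterations = res$counts[1], gradient_norm = sqrt(sum(cur$score^2)))
}

# ---- public fitting interface ------------------------------------------

prep_reml <- function(grm, cohort, design, drop_empty = FALSE) {
  stopifnot(inherits(grm, "gxs_grm"), inherits(cohort, "gxs_cohort"))
  assert_that(all(cohort$ids %in% grm$ids),
              "every cohort individual needs a GRM entry")
  k <- subset_grm(grm, cohort$ids)$K
  x <- build_design(cohort, design)
  if (drop_empty) x <- x[, colSums(abs(x)) > 0, drop = FALSE]
  qrx <- qr(x)
  assert_that(qrx$rank == ncol(x), "fixed-effect matrix not full column rank")
  list(K = k, y = cohort$y, X = x,
       sex_int = ifelse(cohort$sex == "M", 1L, 2L))
}

finalize_fit <- function(fit, prep, cohort, design) {
  spec <- fit$spec
  theta <- fit$theta
  nat <- spec$map(theta)
  names(nat) <- c("sigma2_g_m", "sigma2_g_f", "cov_g",
                  "sigma2_e_m", "sigma2_e_f")
  j <- spec$jac(theta)
  rho <- nat[["cov_g"]] / sqrt(nat[["sigma2_g_m"]] * nat[["sigma2_g_f"]])

  se_theta <- rep(NA_real_, spec$p)
  cov_nat <- matrix(NA_real_, 5, 5)
  se_derived <- c(h2_m = NA_real_, h2_f = NA_real_, rho = NA_real_)
  if (fit$converged) {
    ai_theta <- crossprod(j, fit$cur$ai %*% j)
    cov_theta <- tryCatch(solve(ai_theta), error = function(e) NULL)
    if (!is.null(cov_theta)) {
      se_theta <- sqrt(pmax(diag(cov_theta), 0))
      cov_nat <- j %*% cov_theta %*% t(j)
      g1 <- nat[["sigma2_g_m"]]; g2 <- nat[["sigma2_g_f"]]
      c12 <- nat[["cov_g"]]
      e1 <- nat[["sigma2_e_m"]]; e2 <- nat[["sigma2_e_f"]]
      dh2m <- c(e1 / (g1 + e1)^2, 0, 0, -g1 / (g1 + e1)^2, 0)
      dh2f <- c(0, e2 / (g2 + e2)^2, 0, 0, -g2 / (g2 + e2)^2)
      drho <- c(-rho / (2 * g1), -rho / (2 * g2), 1 / sqrt(g1 * g2), 0, 0)
      se_derived <- c(
        h2_m = sqrt(max(0, drop(dh2m %*% cov_nat %*% dh2m))),
        h2_f = sqrt(max(0, drop(dh2f %*% cov_nat %*% dh2f))),
        rho = sqrt(max(0, drop(drho %*% cov_nat %*% drho)))
      )
    }
  }
  names(se_theta) <- spec$names
  params <- as.list(nat)
  params$rho <- rho
  params$model <- fit$model
  if (fit$model == "equal_h2") params$lambda <- theta[[3]]
  if (fit$model == "univariate") {
    params$sigma2_g <- theta[[1]]
    params$sigma2_e <- theta[[2]]
  }
  theta_named <- setNames(theta, spec$names)
  boundary <- any(theta <= fit$lower * 10 & is.finite(fit$lower)) ||
    abs(rho) >= 1 - 1e-8
  structure(list(
    model = fit$model,
    params = params,
    theta = theta_named,
    beta = setNames(fit$cur$beta, colnames(prep$X)),
    se = c(se_theta, se_derived),
    cov_nat = cov_nat,
    logLik = fit$cur$ll,
    converged = fit$converged,
    iterations = fit$iterations,
    gradient_norm = fit$gradient_norm,
    boundary = boundary,
    n = length(prep$y),
    n_male = sum(prep$sex_int == 1L),
    n_female = sum(prep$sex_int == 2L),
    ids = cohort$ids,
    design = design,
    Py = fit$cur$py
  ), class = "gxs_reml_fit")
}

#' @export
print.gxs_reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s model), n = %d (%d M / %d F)\n",
              x$model, x$n, x$n_male, x$n_female))
  cat(sprintf("  logLr = %.4f, converged = %s (%d iterations)\n",
              x$logLik, x$converged, x$iterations))
  est <- unlist(x$params[c("sigma2_g_m", "sigma2_g_f", "rho",
                           "sigma2_e_m", "sigma2_e_f")])
  print(round(est, 4))
  invisible(x)
}

theta_from_fit <- function(fit, model) {
  p <- fit$params
  switch(model,
    free = c(p$sigma2_g_m, p$sigma2_g_f, p$cov_g, p$sigma2_e_m, p$sigma2_e_f),
    rho1 = c(p$sigma2_g_m, p$sigma2_g_f, p$sigma2_e_m, p$sigma2_e_f),
    equal_h2 = c(p$sigma2_g_m, p$sigma2_g_f,
                 max((p$sigma2_e_m / p$sigma2_g_m +
                        p$sigma2_e_f / p$sigma2_g_f) / 2, 1e-6),
                 min(max(p$rho, -0.99), 0.99)),
    univariate = c((p$sigma2_g_m + p$sigma2_g_f) / 2,
                   (p$sigma2_e_m + p$sigma2_e_f) / 2)
  )
}

fit_variant <- function(grm, cohort, model, design, init, options) {
  prep <- prep_reml(grm, cohort, design)
  if (inherits(init, "gxs_reml_fit")) init <- theta_from_fit(init, model)
  fit <- reml_engine(prep$K, prep$y, prep$X, prep$sex_int, model,
                     init = init, options = options)
  finalize_fit(fit, prep, cohort, design)
}

#' Fit the unconstrained bivariate sex-stratified model
#'
#' Five variance parameters: sex-specific genetic variances, the cross-sex
#' genetic covariance (reported as the correlation `rho`), and sex-specific
#' residual variances. Fixed effects are a per-sex intercept and per-sex
#' coefficients for every covariate, estimated jointly inside REML.
#'
#' @param grm A `gxs_grm` covering every cohort individual.
#' @param cohort A `gxs_cohort` with both sexes present.
#' @param init Optional starting values (length-5 numeric on the natural
#'   scale, or a previous `gxs_reml_fit`).
#' @param options List overriding engine defaults: `max_iter` (200),
#'   `tol_obj` (1e-8), `tol_par` (1e-6), `restarts` (3), `verbose`.
#' @return A `gxs_reml_fit`.
#' @export
fit_bivariate <- function(grm, cohort, init = NULL, options = list()) {
  fit_variant(grm, cohort, "free", "stratified", init, options)
}

#' Fit the bivariate model constrained to genetic correlation one
#'
#' As [fit_bivariate()] but with the cross-sex genetic covariance fixed at
#' `sqrt(sigma2_g_m * sigma2_g_f)` (four free parameters).
#'
#' @inheritParams fit_bivariate
#' @return A `gxs_reml_fit`.
#' @export
fit_rho1 <- function(grm, cohort, init = NULL, options = list()) {
  fit_variant(grm, cohort, "rho1", "stratified", init, options)
}

#' Fit the bivariate model constrained to equal heritabilities
#'
#' Reparametrized in `(sigma2_m, sigma2_f, lambda, rho)` with genetic
#' variances `sigma2_m`, `sigma2_f` and residual variances
#' `lambda * sigma2_m`, `lambda * sigma2_f`, which enforces
#' `h2_m = h2_f = 1 / (1 + lambda)` exactly.
#'
#' @inheritParams fit_bivariate
#' @return A `gxs_reml_fit`.
#' @export
fit_equal_h2 <- function(grm, cohort, init = NULL, options = list()) {
  fit_variant(grm, cohort, "equal_h2", "stratified", init, options)
}

#' Fit the sex-agnostic univariate model
#'
#' One genetic and one residual variance over the pooled cohort. The fixed
#' effects include a sex main effect and sex-by-covariate interactions, so
#' the mean structure matches the bivariate model exactly.
#'
#' @inheritParams fit_bivariate
#' @return A `gxs_reml_fit`.
#' @export
fit_univariate <- function(grm, cohort, init = NULL, options = list()) {
  if (all(cohort$sex == cohort$sex[1])) {
    # single-sex cohort: plain single-trait fit with its own intercept
    prep <- prep_reml(grm, cohort, "stratified", drop_empty = TRUE)
    fit <- reml_engine(prep$K, prep$y, prep$X, prep$sex_int, "univariate",
                       init = init, options = options)
    return(finalize_fit(fit, prep, cohort, "stratified"))
  }
  fit_variant(grm, cohort, "univariate", "interaction", init, options)
}

#' Restricted log-likelihood at fixed variance parameters
#'
#' Evaluates the bivariate model's restricted log-likelihood at the given
#' natural parameters. The additive constant convention includes the
#' `-(n - p)/2 * log(2*pi)` term, so differences of two evaluations on the
#' same data are free of convention.
#'
#' @param params Named list or vector with `sigma2_g_m`, `sigma2_g_f`,
#'   `rho`, `sigma2_e_m`, `sigma2_e_f` (alternatively `cov_g` in place of
#'   `rho`).
#' @param grm A `gxs_grm`.
#' @param cohort A `gxs_cohort`.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(params, grm, cohort) {
  p <- as.list(params)
  c12 <- if (!is.null(p$cov_g)) p$cov_g else
    p$rho * sqrt(p$sigma2_g_m * p$sigma2_g_f)
  nat <- c(p$sigma2_g_m, p$sigma2_g_f, c12, p$sigma2_e_m, p$sigma2_e_f)
  prep <- prep_reml(grm, cohort, "stratified")
  mi <- which(prep$sex_int == 1L)
  fi <- which(prep$sex_int == 2L)
  r <- eval_reml(nat, prep$K, prep$y, prep$X, mi, fi, deriv = FALSE)
  if (is.null(r)) stop("V is not positive definite at these parameters")
  r$ll
}

#' Sex-specific heritabilities from a REML fit
#'
#' `h2_x = sigma2_g_x / (sigma2_g_x + sigma2_e_x)` per sex, with
#' delta-method standard errors from the fit's parameter covariance.
#'
#' @param fit A converged `gxs_reml_fit`.
#' @return A data.frame with rows `male` and `female` and columns
#'   `h2`, `se`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "gxs_reml_fit"))
  p <- fit$params
  h2m <- p$sigma2_g_m / (p$sigma2_g_m + p$sigma2_e_m)
  h2f <- p$sigma2_g_f / (p$sigma2_g_f + p$sigma2_e_f)
  data.frame(sex = c("male", "female"), h2 = c(h2m, h2f),
             se = unname(fit$se[c("h2_m", "h2_f")]))
}

#' Likelihood ratio test between nested REML fits
#'
#' Statistic `2 * (logLr_full - logLr_constrained)`, clipped at zero, with
#' the P value from the upper tail of the 1-df chi-square distribution.
#' Both fits must have converged on the same data with the same fixed
#' effects.
#'
#' @param fit_full,fit_constrained `gxs_reml_fit` objects; the constrained
#'   model must be nested in the full one.
#' @return List of class `gxs_lrt`: `statistic`, `df`, `p.value`.
#' @export
lrt <- function(fit_full, fit_constrained) {
  stopifnot(inherits(fit_full, "gxs_reml_fit"),
            inherits(fit_constrained, "gxs_reml_fit"))
  if (!fit_full$converged || !fit_constrained$converged) {
    stop(sprintf(
      "refusing LRT on unconverged fit(s): full converged=%s (grad %.2e), constrained converged=%s (grad %.2e)",
      fit_full$converged, fit_full$gradient_norm,
      fit_constrained$converged, fit_constrained$gradient_norm))
  }
  assert_that(fit_full$n == fit_constrained$n,
              "fits must be on the same data")
  stat <- max(0, 2 * (fit_full$logLik - fit_constrained$logLik))
  structure(list(statistic = stat, df = 1L,
                 p.value = pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "gxs_lrt")
}

#' @export
print.gxs_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.4f, df = %d, P = %.3g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Full gene-by-sex analysis of one phenotype
#'
#' Runs the unconstrained bivariate fit plus the two constrained fits
#' (genetic correlation fixed at one; equal heritabilities) and returns
#' sex-specific heritabilities, the cross-sex genetic correlation (all with
#' standard errors) and the two 1-df likelihood ratio test P values.
#' Constrained fits are initialized from the unconstrained estimates.
#'
#' @param grm A `gxs_grm`.
#' @param cohort A `gxs_cohort`.
#' @param options Engine options passed to the fits.
#' @return An object of class `gxs_result` with fields `h2_m`, `se_h2_m`,
#'   `h2_f`, `se_h2_f`, `rg`, `se_rg`, `p_rg`, `p_h2` and the three fits
#'   under `$fits`.
#' @export
gxs_report <- function(grm, cohort, options = list()) {
  fit_free <- fit_bivariate(grm, cohort, options = options)
  fit_r1 <- fit_rho1(grm, cohort, init = fit_free, options = options)
  fit_eq <- fit_equal_h2(grm, cohort, init = fit_free, options = options)
  # non-convexity guard: a constrained optimum above the free one means
  # the free fit stopped short of the global optimum; restart it from the
  # better constrained solution (which lies inside the free parameter
  # space) and keep the best
  for (con in list(fit_r1, fit_eq)) {
    if (con$logLik > fit_free$logLik) {
      cand <- fit_bivariate(grm, cohort, init = theta_from_fit(con, "free"),
                            options = options)
      if (cand$logLik > fit_free$logLik) fit_free <- cand
    }
  }
  h2 <- heritability(fit_free)
  structure(list(
    h2_m = h2$h2[1], se_h2_m = h2$se[1],
    h2_f = h2$h2[2], se_h2_f = h2$se[2],
    rg = fit_free$params$rho, se_rg = unname(fit_free$se["rho"]),
    p_rg = lrt(fit_free, fit_r1)$p.value,
    p_h2 = lrt(fit_free, fit_eq)$p.value,
    fits = list(free = fit_free, rho1 = fit_r1, equal_h2 = fit_eq)
  ), class = "gxs_result")
}

#' @export
print.gxs_result <- function(x, ...) {
  cat("Gene-by-sex analysis\n")
  cat(sprintf("  %-6s %8s %8s\n", "", "Est.", "S.E."))
  cat(sprintf("  %-6s %8.3f %8.3f\n", "h2_m", x$h2_m, x$se_h2_m))
  cat(sprintf("  %-6s %8.3f %8.3f\n", "h2_f", x$h2_f, x$se_h2_f))
  cat(sprintf("  %-6s %8.3f %8.3f\n", "r_g", x$rg, x$se_rg))
  cat(sprintf("  P(r_g != 1)    = %.3g\n", x$p_rg))
  cat(sprintf("  P(h2_m != h2_f) = %.3g\n", x$p_h2))
  invisible(x)
}

#' One-row data.frame view of a gene-by-sex result
#'
#' @param x A `gxs_result`.
#' @param ... Unused.
#' @return A one-row data.frame mirroring the usual reporting layout
#'   (estimate and standard error for `h2_m`, `h2_f`, `r_g`, then the two
#'   LRT P values).
#' @export
as.data.frame.gxs_result <- function(x, ...) {
  data.frame(h2_m = x$h2_m, se_h2_m = x$se_h2_m,
             h2_f = x$h2_f, se_h2_f = x$se_h2_f,
             rg = x$rg, se_rg = x$se_rg,
             p_rg = x$p_rg, p_h2 = x$p_h2)
}
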