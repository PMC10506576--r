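#' Fit the listener response model by marginal maximum likelihood
#'
#' Recovers the four population parameters of the simulator's logistic
#' response model (`mu_trait`, `sd_trait`, `beta_lowcut`, `beta_series`) from
#' a response table. The per-participant latent trait is integrated out by
#' Gauss-Hermite quadrature and the marginal log-likelihood maximised with
#' `optim` (BFGS on an unconstrained parametrisation, `log sd`). Standard
#' errors come from the inverse observed information at the optimum.
#'
#' @param responses A response tibble in the [simulate_cohort()] schema.
#' @param nodes Number of Gauss-Hermite quadrature nodes.
#' @param start Optional named start values
#'   (`mu_trait`, `sd_trait`, `beta_lowcut`, `beta_series`).
#'
#' @return An object of class `listener_fit` with [tidy()] and [glance()]
#'   methods.
#'
#' @export
fit_listener_model <- function(responses, nodes = 21L, start = NULL) {
  tallies <- responses |>
    dplyr::count(.data$participant_id, .data$condition,
                 spectral = .data$response == "spectral") |>
    tidyr::pivot_wider(names_from = "spectral", values_from = "n",
                       names_prefix = "r", values_fill = 0L)
  if (!"rTRUE" %in% names(tallies)) tallies$rTRUE <- 0L
  if (!"rFALSE" %in% names(tallies)) tallies$rFALSE <- 0L

  conds <- condition_levels()
  sp <- matrix(0, nrow = length(unique(tallies$participant_id)),
               ncol = length(conds),
               dimnames = list(NULL, conds))
  f0 <- sp
  ids <- sort(unique(tallies$participant_id))
  sp[cbind(match(tallies$participant_id, ids),
           match(tallies$condition, conds))] <- tallies$rTRUE
  f0[cbind(match(tallies$participant_id, ids),
           match(tallies$condition, conds))] <- tallies$rFALSE

  k <- as.integer(substr(conds, 2L, 2L)) - 1L
  is_y <- as.integer(substr(conds, 1L, 1L) == "Y")
  gh <- pracma::gaussHermite(nodes)

  negll <- function(par) {
    mu <- par[1L]; sd <- exp(par[2L]); bk <- par[3L]; by <- par[4L]
    traits <- mu + sqrt(2) * sd * gh$x            # nodes
    eta <- outer(traits, bk * k + by * is_y, "+") # nodes x conds
    logp <- stats::plogis(eta, log.p = TRUE)
    logq <- stats::plogis(-eta, log.p = TRUE)
    # participants x nodes: conditional log-likelihood given each node
    ll_cond <- tcrossprod(sp, logp) + tcrossprod(f0, logq)
    m <- apply(ll_cond, 1L, max)
    lik <- exp(ll_cond - m) %*% (gh$w / sqrt(pi))
    -sum(m + log(lik))
  }

  if (is.null(start)) {
    start <- c(mu_trait = 0, sd_trait = 1, beta_lowcut = 0, beta_series = 0)
  }
  par0 <- c(start[["mu_trait"]], log(start[["sd_trait"]]),
            start[["beta_lowcut"]], start[["beta_series"]])
  opt <- optim(par0, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500L))

  est <- c(opt$par[1L], exp(opt$par[2L]), opt$par[3L], opt$par[4L])
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 4L, 4L)
  })
  se <- sqrt(pmax(diag(vc), 0))
  se[2L] <- se[2L] * est[2L]  # delta method, log sd -> sd
  names(est) <- names(se) <-
    c("mu_trait", "sd_trait", "beta_lowcut", "beta_series")

  structure(
    list(
      estimate = est, std_error = se, logLik = -opt$value,
      n_participants = length(ids),
      n_responses = sum(sp) + sum(f0),
      convergence = opt$convergence
    ),
    class = "listener_fit"
  )
}

#' @export
print.listener_fit <- function(x, ...) {
  cat("<listener_fit> marginal ML, ", x$n_participants, " participants\n",
      sep = "")
  print(round(rbind(estimate = x$estimate, std.error = x$std_error), 4))
  invisible(x)
}

#' @rdname fit_listener_model
#' @param x A `listener_fit`.
#' @param ... Unused.
#' @export
tidy.listener_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$std_error)
  )
}

#' @rdname fit_listener_model
#' @export
glance.listener_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik,
    nobs = x$n_responses,
    n_participants = x$n_participants,
    converged = x$convergence == 0L
  )
}
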