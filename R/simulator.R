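# Correlated binary indicator generation: assemble the target binary
# correlation matrix from component correlations, solve the matching
# latent Gaussian correlations pair by pair, and dichotomize multivariate
# normal draws at the marginal thresholds.

#' Structural classification of indicator column pairs
#'
#' Enumerates every unordered pair of indicator columns and assigns it to
#' its correlation class.  Objective 1 (columns: radiologist pairs in
#' [reader_pairs()] order, then device scores `s_1..s_m`): classes
#' `rho_r1` (r-pairs sharing one reader), `rho_r2` (disjoint r-pairs),
#' `rho_s1` (r-pair and s sharing the reader), `rho_s2` (no shared
#' reader), `rho_ss`.  Objective 2 (columns `x_1..x_m`, `y_1..y_m`):
#' classes `rho_xx`, `rho_yy`, `rho_xy`.
#'
#' @param objective 1 or 2.
#' @param m readers (per group for objective 2).
#' @return list with `labels` (column names), `class_names`, and `pairs`
#'   (data frame with column indices `a`, `b` and their `class`).
#' @export
indicator_pair_classes <- function(objective, m) {
  objective <- match.arg(as.character(objective), c("1", "2"))
  if (objective == "1") {
    pr_idx <- reader_pairs(m)
    K <- nrow(pr_idx)
    labels <- c(sprintf("r_%d_%d", pr_idx[, 1], pr_idx[, 2]),
                sprintf("s_%d", seq_len(m)))
    d <- K + m
    # members[[k]]: readers involved in column k (pair or singleton)
    members <- c(lapply(seq_len(K), function(k) pr_idx[k, ]),
                 lapply(seq_len(m), function(j) j))
    is_r <- c(rep(TRUE, K), rep(FALSE, m))
    out <- vector("list", d * (d - 1L) / 2L)
    pos <- 0L
    for (a in seq_len(d - 1L)) {
      for (b in (a + 1L):d) {
        shared <- length(intersect(members[[a]], members[[b]]))
        cl <- if (is_r[a] && is_r[b]) {
          if (shared == 1L) "rho_r1" else "rho_r2"
        } else if (!is_r[a] && !is_r[b]) {
          "rho_ss"
        } else {
          if (shared == 1L) "rho_s1" else "rho_s2"
        }
        pos <- pos + 1L
        out[[pos]] <- list(a = a, b = b, class = cl)
      }
    }
    pairs <- data.frame(a = vapply(out, `[[`, integer(1), "a"),
                        b = vapply(out, `[[`, integer(1), "b"),
                        class = vapply(out, `[[`, character(1), "class"),
                        stringsAsFactors = FALSE)
    list(labels = labels,
         class_names = c("rho_r1", "rho_r2", "rho_s1", "rho_s2", "rho_ss"),
         pairs = pairs)
  } else {
    labels <- c(sprintf("x_%d", seq_len(m)), sprintf("y_%d", seq_len(m)))
    d <- 2L * m
    grp <- rep(c("x", "y"), each = m)
    idx <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
    cl <- ifelse(grp[idx[, 1]] == grp[idx[, 2]],
                 ifelse(grp[idx[, 1]] == "x", "rho_xx", "rho_yy"),
                 "rho_xy")
    pairs <- data.frame(a = idx[, 1], b = idx[, 2], class = cl,
                        stringsAsFactors = FALSE)
    list(labels = labels, class_names = c("rho_xx", "rho_yy", "rho_xy"),
         pairs = pairs)
  }
}

#' Feasibility bounds for a binary correlation
#'
#' A correlation between Bernoulli variables with success probabilities
#' `p_j`, `p_k` is constrained by the Frechet bounds on their joint
#' distribution.
#'
#' @param p_j,p_k marginal success probabilities in (0, 1).
#' @return named vector `c(lower, upper)`.
#' @export
binary_corr_bounds <- function(p_j, p_k) {
  q_j <- 1 - p_j
  q_k <- 1 - p_k
  c(lower = max(-sqrt(p_j * p_k / (q_j * q_k)), -sqrt(q_j * q_k / (p_j * p_k))),
    upper = min(sqrt(p_j * q_k / (p_k * q_j)), sqrt(p_k * q_j / (p_j * q_k))))
}

#' Bivariate standard normal upper orthant probability
#'
#' `P(Z1 > a, Z2 > b)` for standard normal `(Z1, Z2)` with correlation
#' `rho`, computed by reducing to a one-dimensional integral
#' `int_a^Inf phi(z) Phibar((b - rho z)/sqrt(1 - rho^2)) dz` evaluated by
#' adaptive quadrature.
#'
#' @param a,b thresholds.
#' @param rho latent correlation in (-1, 1); the limits -1 and 1 are
#'   handled analytically.
#' @return orthant probability.
#' @export
bvn_upper_prob <- function(a, b, rho) {
  if (rho >= 1) return(pnorm(max(a, b), lower.tail = FALSE))
  if (rho <= -1) return(max(0, pnorm(-b) - pnorm(a)))
  if (rho == 0) return(pnorm(a, lower.tail = FALSE) * pnorm(b, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  integrate(function(z) dnorm(z) * pnorm((b - rho * z) / s, lower.tail = FALSE),
            lower = a, upper = Inf,
            rel.tol = 1e-12, abs.tol = 1e-14, subdivisions = 400L)$value
}

#' Solve the latent Gaussian correlation matching a binary correlation
#'
#' Finds the correlation `rho*` of a latent bivariate standard normal
#' vector such that thresholding each coordinate at the upper-tail
#' quantile of its marginal produces binary variables with correlation
#' `rho_b`: solves `Phi2(tau_j, tau_k; rho*) = rho_b sqrt(p_j q_j p_k q_k)
#' + p_j p_k` by bracketed root finding (the orthant probability is
#' increasing in `rho*`).
#'
#' @param p_j,p_k binary marginals in (0, 1).
#' @param rho_b target binary correlation, strictly inside
#'   [binary_corr_bounds()].
#' @param tol root tolerance on the latent correlation.
#' @return latent normal correlation `rho*`.
#' @examples
#' solve_latent_correlation(0.5, 0.5, 0.5)  # sin(pi/4) = 0.7071...
#' @export
solve_latent_correlation <- function(p_j, p_k, rho_b, tol = 1e-12) {
  if (rho_b == 0) return(0)
  bounds <- binary_corr_bounds(p_j, p_k)
  if (rho_b <= bounds["lower"] || rho_b >= bounds["upper"]) {
    stop(sprintf(paste0("binary correlation %.4f infeasible for marginals ",
                        "(%.3f, %.3f): bounds are (%.4f, %.4f)"),
                 rho_b, p_j, p_k, bounds["lower"], bounds["upper"]),
         call. = FALSE)
  }
  tau_j <- qnorm(p_j, lower.tail = FALSE)
  tau_k <- qnorm(p_k, lower.tail = FALSE)
  target <- rho_b * sqrt(p_j * (1 - p_j) * p_k * (1 - p_k)) + p_j * p_k
  f <- function(r) bvn_upper_prob(tau_j, tau_k, r) - target
  lim <- 1 - 1e-9
  uniroot(f, lower = -lim, upper = lim, tol = tol,
          f.lower = bvn_upper_prob(tau_j, tau_k, -1) - target,
          f.upper = bvn_upper_prob(tau_j, tau_k, 1) - target)$root
}

#' Assemble the indicator layout for simulation
#'
#' Builds the full target binary correlation matrix for the indicator
#' vector of one subject from the component correlations, together with
#' the per-indicator marginals.  Every off-diagonal entry is determined by
#' its structural class ([indicator_pair_classes()]); each entry is
#' validated against its binary feasibility bounds.
#'
#' @param objective 1 or 2.
#' @param m readers (per group for objective 2).
#' @param marginals length-2 numeric: `c(pr, ps)` for objective 1 (r- and
#'   s-indicator marginals), `c(px, py)` for objective 2.
#' @param components [component_correlations1()] or
#'   [component_correlations2()] object with matching `m`.
#' @return object of class `indicator_layout`: `objective`, `m`,
#'   `labels`, `marginals` (per indicator), `binary_corr`, `components`.
#' @export
assemble_layout <- function(objective, m, marginals, components) {
  objective <- as.integer(match.arg(as.character(objective), c("1", "2")))
  if (length(marginals) != 2L || any(marginals <= 0) || any(marginals >= 1)) {
    stop("marginals must be two probabilities strictly inside (0, 1)",
         call. = FALSE)
  }
  if (objective == 1L) {
    stopifnot(inherits(components, "component_correlations1"))
  } else {
    stopifnot(inherits(components, "component_correlations2"))
  }
  if (components$m != m) {
    stop(sprintf("components were built for m = %d, layout requests m = %d",
                 components$m, m), call. = FALSE)
  }
  cls <- indicator_pair_classes(objective, m)
  d <- length(cls$labels)
  marg <- if (objective == 1L) {
    c(rep(marginals[1], m * (m - 1) / 2), rep(marginals[2], m))
  } else {
    c(rep(marginals[1], m), rep(marginals[2], m))
  }
  names(marg) <- cls$labels
  R <- diag(d)
  for (k in seq_len(nrow(cls$pairs))) {
    a <- cls$pairs$a[k]
    b <- cls$pairs$b[k]
    rho <- components[[cls$pairs$class[k]]]
    bounds <- binary_corr_bounds(marg[a], marg[b])
    if (rho <= bounds["lower"] || rho >= bounds["upper"]) {
      stop(sprintf(paste0("target correlation %.4f for pair (%s, %s) violates ",
                          "binary feasibility bounds (%.4f, %.4f)"),
                   rho, cls$labels[a], cls$labels[b],
                   bounds["lower"], bounds["upper"]), call. = FALSE)
    }
    R[a, b] <- R[b, a] <- rho
  }
  dimnames(R) <- list(cls$labels, cls$labels)
  structure(
    list(objective = objective, m = m, labels = cls$labels, marginals = marg,
         binary_corr = R, components = components),
    class = "indicator_layout"
  )
}

#' @export
print.indicator_layout <- function(x, ...) {
  cat(sprintf("Indicator layout, Objective %d: m = %d, dimension %d\n",
              x$objective, x$m, length(x$labels)))
  cat(sprintf("  marginals: %s\n",
              paste(sprintf("%.3f", unique(x$marginals)), collapse = ", ")))
  invisible(x)
}

#' Latent Gaussian model for an indicator layout
#'
#' Solves the latent correlation for every pair (cached per unique
#' marginal/target combination), repairs the assembled latent matrix to
#' positive semidefiniteness by eigenvalue clipping (floor 1e-10) with
#' re-normalization to unit diagonal, and precomputes the Cholesky-type
#' factor used for simulation.  The maximum entry perturbation introduced
#' by the repair is recorded in `repair_delta`; a perturbation above 0.01
#' raises a warning.
#'
#' @param layout [assemble_layout()] result.
#' @return object of class `latent_model`: `thresholds`, `latent_corr`,
#'   `factor` (matrix `L` with `crossprod(L) = latent_corr`),
#'   `repair_delta`.
#' @export
latent_model <- function(layout) {
  stopifnot(inherits(layout, "indicator_layout"))
  marg <- layout$marginals
  d <- length(marg)
  tau <- qnorm(marg, lower.tail = FALSE)
  cache <- new.env(parent = emptyenv())
  Lat <- diag(d)
  R <- layout$binary_corr
  for (a in seq_len(d - 1L)) {
    for (b in (a + 1L):d) {
      rho_b <- R[a, b]
      key <- sprintf("%.17g|%.17g|%.17g", min(marg[a], marg[b]),
                     max(marg[a], marg[b]), rho_b)
      if (is.null(cache[[key]])) {
        cache[[key]] <- solve_latent_correlation(marg[a], marg[b], rho_b)
      }
      Lat[a, b] <- Lat[b, a] <- cache[[key]]
    }
  }
  eig <- eigen(Lat, symmetric = TRUE)
  repair_delta <- 0
  if (min(eig$values) < 1e-10) {
    vals <- pmax(eig$values, 1e-10)
    fixed <- eig$vectors %*% (vals * t(eig$vectors))
    D <- 1 / sqrt(diag(fixed))
    fixed <- fixed * tcrossprod(D)
    repair_delta <- max(abs(fixed - Lat))
    if (repair_delta > 0.01) {
      warning(sprintf("PSD repair changed a latent correlation by %.4f (> 0.01)",
                      repair_delta))
    }
    Lat <- fixed
  }
  L <- tryCatch(chol(Lat), error = function(e) {
    chol(Lat + diag(1e-8, d))
  })
  structure(
    list(thresholds = tau, latent_corr = Lat, factor = L,
         repair_delta = repair_delta, layout = layout),
    class = "latent_model"
  )
}

# one batch of n indicator rows from a prepared latent model (does not
# touch the seed; callers manage RNG state)
.draw_indicators <- function(model, n) {
  d <- length(model$thresholds)
  Z <- matrix(rnorm(n * d), n, d) %*% model$factor
  ind <- (Z > rep(model$thresholds, each = n)) + 0
  colnames(ind) <- model$layout$labels
  ind
}

#' Simulate a correlated binary concordance dataset
#'
#' Generates `n` i.i.d. indicator vectors by drawing latent multivariate
#' normal vectors and dichotomizing coordinate `k` at the upper-tail
#' threshold of its marginal (`indicator = 1` iff latent value exceeds
#' `qnorm(p_k, lower.tail = FALSE)`).  Latent pairwise correlations are
#' solved so the induced *binary* correlations match the layout's targets
#' exactly (pairwise); higher-order joint structure is not controlled.
#'
#' @param layout [assemble_layout()] result.
#' @param n subjects to simulate.
#' @param seed RNG seed (integer) for reproducibility; `NULL` continues
#'   the current RNG stream.
#' @param model optional precomputed [latent_model()] for `layout`
#'   (saves the latent solve when simulating repeatedly).
#' @return `concordance_data1` or `concordance_data2` object with
#'   attributes `seed` and `repair_delta`.
#' @export
simulate_dataset <- function(layout, n, seed = NULL, model = NULL) {
  stopifnot(inherits(layout, "indicator_layout"))
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  if (is.null(model)) model <- latent_model(layout)
  if (!is.null(seed)) set.seed(seed)
  ind <- .draw_indicators(model, n)
  m <- layout$m
  out <- if (layout$objective == 1L) {
    K <- m * (m - 1L) / 2L
    concordance_data1(ind[, seq_len(K), drop = FALSE],
                      ind[, K + seq_len(m), drop = FALSE])
  } else {
    concordance_data2(ind[, seq_len(m), drop = FALSE],
                      ind[, m + seq_len(m), drop = FALSE])
  }
  attr(out, "seed") <- seed
  attr(out, "repair_delta") <- model$repair_delta
  out
}
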