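#' Questionnaire scale definitions
#'
#' Declares the structure the item simulator and the scorers share: number of
#' 4-point Likert items, which latent trait drives them, the Cronbach's alpha
#' the generated item set should exhibit, and the target per-item mean. The
#' built-in definitions cover the LSRP primary subscale (16 items), the LSRP
#' secondary subscale (10 items) and the BIS-11 (30 items); their default
#' alphas (0.80, 0.63, 0.84) and per-item means are the study calibration.
#'
#' @param name Scale label.
#' @param n_items Number of items.
#' @param latent Name of the driving latent trait column in the traits table.
#' @param reliability Cronbach's alpha target in (0, 1].
#' @param item_mean Target mean response per item on the 1-4 scale.
#' @return An object of class `rtcit_scale_def`.
#' @export
scale_def <- function(name, n_items, latent, reliability, item_mean = 2.5) {
  if (reliability <= 0 || reliability > 1) {
    stop("reliability must lie in (0, 1]", call. = FALSE)
  }
  if (n_items < 2) stop("a scale needs at least 2 items", call. = FALSE)
  if (item_mean <= 1 || item_mean >= 4) {
    stop("item_mean must lie strictly inside (1, 4)", call. = FALSE)
  }
  structure(list(name = name, n_items = as.integer(n_items), latent = latent,
                 reliability = reliability, item_mean = item_mean),
            class = "rtcit_scale_def")
}

#' @rdname scale_def
#' @param config An [trait_model_config()] supplying reliability targets.
#' @export
default_scale_defs <- function(config = trait_model_config()) {
  rel <- config$reliabilities
  list(
    lsrp_primary = scale_def("lsrp_primary", 16, "z_primary",
                             rel[["lsrp_primary"]], item_mean = 28.34 / 16),
    lsrp_secondary = scale_def("lsrp_secondary", 10, "z_secondary",
                               rel[["lsrp_secondary"]], item_mean = 19.03 / 10),
    bis = scale_def("bis", 30, "z_impulsivity", rel[["bis"]],
                    item_mean = 63.03 / 30)
  )
}

# Spearman-Brown style inversion: the inter-item correlation a k-item scale
# needs to reach a given alpha
alpha_to_interitem_r <- function(alpha, k) {
  alpha / (k - alpha * (k - 1))
}

# Thresholds (3 cut points, unit spacing) shifted so the discretised standard
# normal has the requested mean on the 1..4 scale.
item_thresholds <- function(item_mean) {
  f <- function(c) {
    tau <- c + c(-1, 0, 1)
    (1 + sum(1 - stats::pnorm(tau))) - item_mean
  }
  c_star <- stats::uniroot(f, c(-4, 4), tol = 1e-10)$root
  c_star + c(-1, 0, 1)
}

# Variance of a standard normal discretised at thresholds tau into 1..k+1
discretised_item_var <- function(tau) {
  p <- diff(c(0, stats::pnorm(tau), 1))
  scores <- seq_along(p)
  sum(p * scores^2) - sum(p * scores)^2
}

# P(X > a, Y > b) for standard bivariate normal with correlation r
binorm_upper <- function(a, b, r) {
  if (abs(r) < 1e-12) return((1 - stats::pnorm(a)) * (1 - stats::pnorm(b)))
  s <- sqrt(1 - r^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((r * x - b) / s)
  stats::integrate(f, a, Inf, rel.tol = 1e-10)$value
}

# Exact correlation between two discretised standard normals whose latent
# correlation is r, thresholds tau1 / tau2.
discretised_corr <- function(r, tau1, tau2 = tau1) {
  if (abs(r) < 1e-12) return(0)
  cov <- 0
  for (a in tau1) {
    for (b in tau2) {
      cov <- cov + binorm_upper(a, b, r) -
        (1 - stats::pnorm(a)) * (1 - stats::pnorm(b))
    }
  }
  cov / sqrt(discretised_item_var(tau1) * discretised_item_var(tau2))
}

# Latent inter-item correlation needed so the DISCRETISED items show r_disc
latent_interitem_r <- function(r_disc, tau) {
  if (r_disc <= 0) return(0)
  upper <- 0.995
  if (r_disc >= discretised_corr(upper, tau)) return(upper)
  stats::uniroot(function(r) discretised_corr(r, tau) - r_disc,
                 c(1e-6, upper), tol = 1e-9)$root
}

#' Generate item-level Likert responses from latent traits
#'
#' Each item is a thresholded noisy copy of the participant's latent trait:
#' `y = loading * z + sqrt(1 - loading^2) * noise`, cut at three thresholds
#' into responses 1-4. The loading is chosen so the DISCRETISED items reach
#' the scale's Cronbach's alpha target: the inter-item correlation implied by
#' alpha is mapped back through the exact correlation function of two
#' thresholded bivariate normals before being converted to a loading, so the
#' coarsening of the 4-point response scale does not attenuate the realised
#' reliability. Thresholds are placed to match the scale's per-item mean.
#'
#' @param traits Participant table from [sample_traits()].
#' @param scale An [scale_def()] object.
#' @return Integer matrix (participants x items) of responses in 1..4, with
#'   column names `<name>_item_01`, ...
#' @examples
#' set.seed(1)
#' tr <- sample_traits(100, trait_model_config())
#' items <- generate_item_responses(tr, default_scale_defs()$lsrp_secondary)
#' @export
generate_item_responses <- function(traits, scale) {
  stopifnot(inherits(scale, "rtcit_scale_def"))
  z <- traits[[scale$latent]]
  if (is.null(z)) {
    stop("traits table lacks latent column '", scale$latent, "'",
         call. = FALSE)
  }
  n <- length(z)
  k <- scale$n_items
  tau <- item_thresholds(scale$item_mean)
  r_disc <- alpha_to_interitem_r(scale$reliability, k)
  loading <- sqrt(latent_interitem_r(r_disc, tau))

  noise <- matrix(stats::rnorm(n * k, sd = sqrt(1 - loading^2)), n, k)
  y <- loading * z + noise
  resp <- matrix(1L, n, k)
  for (t in tau) resp <- resp + (y > t)
  colnames(resp) <- sprintf("%s_item_%02d", scale$name, seq_len(k))
  resp
}

#' Generate post-test subjective ratings
#'
#' Probe and irrelevant significance ratings (1-9 scale) and motivation and
#' felt-impulsivity ratings (1-10 scale), drawn from normal distributions with
#' the configured means and SDs, rounded to integers and clipped to their
#' scales.
#'
#' @param traits Participant table from [sample_traits()] (supplies n and
#'   participant ids).
#' @param config An [trait_model_config()] with `rating_means`/`rating_sds`.
#' @return Tibble with `participant_id` and columns
#'   `rating_probe_significance`, `rating_irrelevant_significance`,
#'   `rating_motivation`, `rating_impulsivity`.
#' @export
generate_ratings <- function(traits, config = trait_model_config()) {
  n <- nrow(traits)
  m <- config$rating_means
  s <- config$rating_sds
  draw <- function(key, lo, hi) {
    pmin(pmax(round(stats::rnorm(n, m[[key]], s[[key]])), lo), hi)
  }
  tibble::tibble(
    participant_id = traits$participant_id,
    rating_probe_significance = draw("probe", 1, 9),
    rating_irrelevant_significance = draw("irrelevant", 1, 9),
    rating_motivation = draw("motivation", 1, 10),
    rating_impulsivity = draw("impulsivity", 1, 10)
  )
}
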