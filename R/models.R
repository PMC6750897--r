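#' Divergence-model parameter sets
#'
#' Constructs a validated parameter object for one of the three models of
#' long-term pairwise sequence divergence between orthologs:
#'
#' * **M1** — equal, independent substitution rates across sites, no back
#'   substitutions: identity decays as `100 * exp(-R0 * t)`.
#' * **M2** — as M1, plus a minimal fraction of identical sites at long
#'   times: `Y0 + (100 - Y0) * exp(-R0 * t)`. The floor `Y0` is
#'   interpretable as `100 / a`, the inverse of the effective number of
#'   amino-acid types accepted per site (see [alphabet_to_limit()]).
#' * **M3** — gamma-distributed substitution rates across sites with shape
#'   `alpha`: `100 * (R0 * t / alpha + 1)^(-alpha)`.
#'
#' Identity is expressed in percent throughout; time in billions of years
#' (Gy).
#'
#' @param model One of `"M1"`, `"M2"`, `"M3"`.
#' @param R0 Average substitution-rate parameter (per Gy), `> 0`.
#' @param Y0 Long-term identity floor in percent, in `[0, 100]` (M2 only).
#' @param alpha Gamma shape parameter, `> 0` (M3 only).
#' @return A list of class `"div_model_params"` with elements `model`,
#'   `R0`, and (as applicable) `Y0`, `alpha`.
#' @examples
#' model_params("M2", R0 = 1.5, Y0 = 40)
#' @export
model_params <- function(model = c("M1", "M2", "M3"), R0, Y0 = NULL, alpha = NULL) {
  model <- match.arg(model)
  if (!is.numeric(R0) || length(R0) != 1 || !is.finite(R0) || R0 <= 0) {
    abort("`R0` must be a single positive number.", class = "divlimit_invalid_param")
  }
  p <- list(model = model, R0 = R0)
  if (model == "M2") {
    if (is.null(Y0) || !is.numeric(Y0) || length(Y0) != 1 ||
        !is.finite(Y0) || Y0 < 0 || Y0 > 100) {
      abort("M2 requires `Y0` in [0, 100].", class = "divlimit_invalid_param")
    }
    p$Y0 <- Y0
  } else if (model == "M3") {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1 ||
        !is.finite(alpha) || alpha <= 0) {
      abort("M3 requires `alpha` > 0.", class = "divlimit_invalid_param")
    }
    p$alpha <- alpha
  }
  structure(p, class = "div_model_params")
}

#' @export
print.div_model_params <- function(x, ...) {
  extra <- switch(x$model,
    M1 = "",
    M2 = sprintf(", Y0 = %.4g%%", x$Y0),
    M3 = sprintf(", alpha = %.4g", x$alpha)
  )
  cat(sprintf("<div_model_params %s: R0 = %.4g/Gy%s>\n", x$model, x$R0, extra))
  invisible(x)
}

as_model_params <- function(params) {
  if (inherits(params, "div_model_params")) return(params)
  if (inherits(params, "div_fit")) return(params$params)
  abort("Expected a `div_model_params` or `div_fit` object.",
        class = "divlimit_invalid_param")
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative and finite.", class = "divlimit_invalid_param")
  }
  t
}

#' Evaluate a divergence model
#'
#' Expected percent sequence identity between a pair of orthologs after
#' divergence time `t` under the chosen model (see [model_params()]).
#'
#' @param params A [model_params()] object (or a fitted [fit_divergence_model()]
#'   object, whose parameters are used).
#' @param t Divergence time(s) in Gy, `>= 0`; vectorized.
#' @return Numeric vector of identities in percent.
#' @examples
#' evaluate_model(model_params("M1", R0 = log(2)), t = 1) # 50
#' @export
evaluate_model <- function(params, t) {
  p <- as_model_params(params)
  t <- check_time(t)
  switch(p$model,
    M1 = 100 * exp(-p$R0 * t),
    M2 = p$Y0 + (100 - p$Y0) * exp(-p$R0 * t),
    M3 = 100 * (p$R0 * t / p$alpha + 1)^(-p$alpha)
  )
}

#' Instantaneous divergence rate
#'
#' The rate of decrease of percent identity per Gy, `-dy/dt`, at divergence
#' time `t`. For the gamma-rates model this is
#' `100 * R0 * (R0 * t / alpha + 1)^(-alpha - 1)`; the closed forms for M1
#' and M2 are provided for completeness.
#'
#' @inheritParams evaluate_model
#' @return Non-negative numeric vector (percent identity lost per Gy).
#' @export
divergence_rate <- function(params, t) {
  p <- as_model_params(params)
  t <- check_time(t)
  switch(p$model,
    M1 = 100 * p$R0 * exp(-p$R0 * t),
    M2 = (100 - p$Y0) * p$R0 * exp(-p$R0 * t),
    M3 = 100 * p$R0 * (p$R0 * t / p$alpha + 1)^(-p$alpha - 1)
  )
}

#' Expansion rate of the protein universe
#'
#' Divergence rate expressed as a function of fractional protein distance
#' `D = 1 - y/100` rather than time, under the gamma-rates model:
#' `dD/dt = R0 * (1 - D)^((alpha + 1) / alpha)`. Equals
#' `divergence_rate(t(D)) / 100` where `t(D)` inverts the M3 identity curve.
#'
#' @param params A [model_params()] object with `model = "M3"`.
#' @param D Fractional distance(s) in `[0, 1)`; vectorized.
#' @return `dD/dt` in fractional distance per Gy.
#' @export
expansion_rate <- function(params, D) {
  p <- as_model_params(params)
  if (p$model != "M3") {
    abort("`expansion_rate()` is defined for the gamma-rates model (M3).",
          class = "divlimit_invalid_param")
  }
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0) || any(D >= 1)) {
    abort("`D` must lie in [0, 1).", class = "divlimit_domain_error")
  }
  p$R0 * (1 - D)^((p$alpha + 1) / p$alpha)
}

#' Factor by which the divergence rate has declined by time t
#'
#' `divergence_rate(0) / divergence_rate(t)`; for the gamma-rates model this
#' is `(R0 * t / alpha + 1)^(alpha + 1)` and grows monotonically with `t`.
#'
#' @inheritParams evaluate_model
#' @return Numeric vector of ratios `>= 1`.
#' @export
rate_decline_factor <- function(params, t) {
  divergence_rate(params, 0) / divergence_rate(params, t)
}

#' Finite-alphabet parameters
#'
#' Parameters of the Jukes-Cantor-type divergence model with a restricted
#' per-site alphabet and back substitutions: `a` allowed residue types per
#' site (real-valued, interpreted as an effective number) and per-site
#' substitution rate `lam` (per Gy).
#'
#' @param a Allowed residue types per site, `> 1`.
#' @param lam Per-site substitution rate, `> 0` (per Gy).
#' @return A list of class `"div_alphabet_params"`.
#' @export
alphabet_params <- function(a, lam) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 1) {
    abort("`a` must be a single number > 1 (degenerate alphabet otherwise).",
          class = "divlimit_degenerate_alphabet")
  }
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam <= 0) {
    abort("`lam` must be a single positive rate.", class = "divlimit_invalid_param")
  }
  structure(list(a = a, lam = lam), class = "div_alphabet_params")
}

#' Map a finite alphabet to the equivalent divergence-floor model
#'
#' A restricted alphabet of `a` types per site with uniform exchange at rate
#' `lam` and back substitutions yields an identity curve mathematically
#' equivalent to the floor model (M2) with `Y0 = 100 / a` and
#' `R0 = 2 * lam * a / (a - 1)`. [limit_to_alphabet()] is the exact inverse.
#'
#' @param ap An [alphabet_params()] object.
#' @return A [model_params()] object with `model = "M2"`.
#' @examples
#' alphabet_to_limit(alphabet_params(a = 4, lam = 0.75)) # Y0 = 25, R0 = 2
#' @export
alphabet_to_limit <- function(ap) {
  stopifnot(inherits(ap, "div_alphabet_params"))
  model_params("M2", R0 = 2 * ap$lam * ap$a / (ap$a - 1), Y0 = 100 / ap$a)
}

#' @rdname alphabet_to_limit
#' @param params A [model_params()] object with `model = "M2"` and `Y0 > 0`.
#' @export
limit_to_alphabet <- function(params) {
  p <- as_model_params(params)
  if (p$model != "M2" || p$Y0 <= 0) {
    abort("Inverse mapping needs an M2 parameter set with Y0 > 0.",
          class = "divlimit_invalid_param")
  }
  a <- 100 / p$Y0
  alphabet_params(a = a, lam = p$R0 * (a - 1) / (2 * a))
}

#' Expected substitutions per site from observed identity
#'
#' Back-substitution-corrected evolutionary distance for a finite alphabet
#' of `a` types: `delta = -((a - 1) / a) * log(1 - (a / (a - 1)) * (1 - y))`,
#' where `y` is the *fractional* identity. The distance is zero at `y = 1`
#' and diverges as `y` approaches the saturation level `1 / a`.
#'
#' @param y Fractional identity in `(1/a, 1]`; vectorized.
#' @param a Alphabet size, `> 1`.
#' @return Expected substitutions per site (vector).
#' @export
expected_substitutions <- function(y, a) {
  if (!is.numeric(a) || length(a) != 1 || a <= 1) {
    abort("`a` must be > 1.", class = "divlimit_degenerate_alphabet")
  }
  if (!is.numeric(y) || any(!is.finite(y)) || any(y > 1)) {
    abort("`y` must be fractional identity <= 1.", class = "divlimit_invalid_param")
  }
  if (any(y <= 1 / a)) {
    abort(sprintf("Identity at or below the saturation level 1/a = %.4g; distance undefined.", 1 / a),
          class = "divlimit_saturation_error")
  }
  -((a - 1) / a) * log(1 - (a / (a - 1)) * (1 - y))
}

#' Serialize model parameters to a flat YAML block
#'
#' @param params A [model_params()] or [alphabet_params()] object.
#' @return A YAML string (flat key-value mapping).
#' @export
params_to_yaml <- function(params) {
  if (inherits(params, "div_alphabet_params")) {
    return(yaml::as.yaml(list(kind = "alphabet", a = params$a, lam = params$lam)))
  }
  p <- as_model_params(params)
  yaml::as.yaml(c(list(kind = "model"), unclass(p)))
}

#' @rdname params_to_yaml
#' @param text A YAML string produced by [params_to_yaml()] (or a file path
#'   when `file = TRUE`).
#' @param file Read `text` as a file path instead of a literal string.
#' @export
params_from_yaml <- function(text, file = FALSE) {
  x <- if (file) yaml::read_yaml(text) else yaml::yaml.load(text)
  kind <- x$kind %||% "model"
  if (identical(kind, "alphabet")) {
    alphabet_params(a = x$a, lam = x$lam)
  } else {
    model_params(x$model, R0 = x$R0, Y0 = x$Y0, alpha = x$alpha)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
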