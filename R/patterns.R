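PATTERN_FAMILIES <- c(
  "uniform", "anterior_gradient", "posterior_gradient",
  "anterior_domain", "posterior_domain", "central_domain", "stripes"
)

GENOTYPES <- c("wt", "bcd_minus", "bcd_2.4x", "hb_minus", "zld_minus")

EFFECTS <- c("none", "loss_to_low", "uniformize", "shift", "ectopic_gain",
             "level_scale")

#' Construct a parametric spatial expression pattern
#'
#' A pattern describes the noise-free mean FPKM of one gene as a function of
#' fractional anteroposterior (AP) position \eqn{x \in [0, 1]} (0 = anterior
#' pole).  Families are parametric stand-ins for the archetypes seen in
#' sliced-embryo data: flat (maternal/ubiquitous) expression, exponential
#' AP gradients, Gaussian expression domains, and raised-cosine stripe
#' patterns (pair-rule-like).
#'
#' @param gene_id character gene identifier.
#' @param family one of `"uniform"`, `"anterior_gradient"`,
#'   `"posterior_gradient"`, `"anterior_domain"`, `"posterior_domain"`,
#'   `"central_domain"`, `"stripes"`.
#' @param amplitude peak expression above baseline, FPKM (>= 0).
#' @param baseline uniform floor expression, FPKM (>= 0).
#' @param center domain center as a fraction of embryo length in `[0, 1]`
#'   (domain families only).
#' @param width Gaussian domain standard deviation as a fraction of embryo
#'   length (> 0; domain families only).
#' @param decay exponential decay length as a fraction of embryo length
#'   (> 0; gradient families only).
#' @param origin position the gradient decays away from (defaults: 0 for
#'   anterior, 1 for posterior gradients); shifts move this origin.
#' @param n_stripes number of stripes (>= 1; stripes family only).
#' @param phase stripe phase offset as a fraction of embryo length.
#' @return An object of class `pattern_spec`.
#' @examples
#' sp <- pattern_spec("g1", "anterior_domain", amplitude = 80, center = 0.2,
#'                    width = 0.08, baseline = 2)
#' evaluate_pattern(sp, c(0.2, 0.9))
#' @export
pattern_spec <- function(gene_id, family, amplitude, baseline = 0,
                         center = NULL, width = NULL, decay = NULL,
                         origin = NULL, n_stripes = NULL, phase = 0) {
  family <- as.character(family)
  if (!family %in% PATTERN_FAMILIES) {
    stop("unknown pattern family: '", family, "'")
  }
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0,
            is.numeric(baseline), length(baseline) == 1L, baseline >= 0)
  params <- list(amplitude = amplitude)
  if (family %in% c("anterior_domain", "posterior_domain", "central_domain")) {
    if (is.null(center) || is.null(width)) {
      stop("domain families require 'center' and 'width'")
    }
    stopifnot(center >= 0, center <= 1, width > 0)
    params$center <- center
    params$width <- width
  } else if (family %in% c("anterior_gradient", "posterior_gradient")) {
    if (is.null(decay)) stop("gradient families require 'decay'")
    stopifnot(decay > 0)
    params$decay <- decay
    params$origin <- if (is.null(origin)) {
      if (family == "anterior_gradient") 0 else 1
    } else origin
  } else if (family == "stripes") {
    if (is.null(n_stripes)) stop("stripes family requires 'n_stripes'")
    stopifnot(n_stripes >= 1)
    params$n_stripes <- as.integer(n_stripes)
    params$phase <- phase
  }
  structure(
    list(gene_id = as.character(gene_id), family = family, params = params,
         baseline = baseline, extra = list()),
    class = "pattern_spec"
  )
}

#' @export
print.pattern_spec <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<pattern_spec> %s: %s (%s; baseline=%g FPKM%s)\n",
              x$gene_id, x$family, ps, x$baseline,
              if (length(x$extra)) sprintf(", +%d ectopic term(s)",
                                           length(x$extra)) else ""))
  invisible(x)
}

#' Evaluate a pattern at fractional AP positions
#'
#' Returns the deterministic, noise-free mean FPKM of the pattern at each
#' position.  Values are always finite and >= 0; the uniform family returns
#' `amplitude + baseline` everywhere.
#'
#' @param spec a [pattern_spec()].
#' @param x numeric vector of positions in `[0, 1]`.
#' @return numeric vector of FPKM values, same length as `x`.
#' @export
evaluate_pattern <- function(spec, x) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (any(x < 0 | x > 1)) stop("positions must lie in [0, 1]")
  p <- spec$params
  a <- p$amplitude
  shape <- switch(spec$family,
    uniform = rep(a, length(x)),
    anterior_gradient = a * exp(-pmax(x - p$origin, 0) / p$decay),
    posterior_gradient = a * exp(-pmax(p$origin - x, 0) / p$decay),
    anterior_domain = ,
    posterior_domain = ,
    central_domain = a * exp(-((x - p$center) / p$width)^2 / 2),
    stripes = a * 0.5 * (1 - cos(2 * pi * p$n_stripes * (x - p$phase))),
    stop("unknown pattern family: '", spec$family, "'")
  )
  v <- shape + spec$baseline
  for (term in spec$extra) {
    v <- v + term$amplitude * exp(-((x - term$center) / term$width)^2 / 2)
  }
  v
}

#' Describe a genotype-dependent perturbation of one gene's pattern
#'
#' Encodes the classes of pattern change observed in anteroposterior
#' patterning mutants: complete loss of expression, a patterned gene
#' becoming uniform, spatial shifts of a domain, ectopic gain of a new
#' expression domain, and pure level scaling without pattern change.
#'
#' @param gene_id gene the effect applies to.
#' @param genotype one of `"wt"`, `"bcd_minus"`, `"bcd_2.4x"`, `"hb_minus"`,
#'   `"zld_minus"`.
#' @param effect one of `"none"`, `"loss_to_low"`, `"uniformize"`,
#'   `"shift"`, `"ectopic_gain"`, `"level_scale"`.
#' @param shift signed shift distance, fraction of embryo length in
#'   `[-1, 1]` (shift effect).
#' @param scale multiplicative factor > 0 (level_scale effect).
#' @param gain_center,gain_width,gain_amplitude parameters of the ectopic
#'   domain (ectopic_gain effect); sensible defaults are derived from the
#'   target pattern when `NULL`.
#' @return An object of class `genotype_effect`.
#' @export
genotype_effect <- function(gene_id, genotype, effect = "none",
                            shift = 0, scale = 1, gain_center = NULL,
                            gain_width = NULL, gain_amplitude = NULL) {
  genotype <- match.arg(genotype, GENOTYPES)
  effect <- match.arg(effect, EFFECTS)
  if (genotype == "wt" && effect != "none") {
    stop("wild-type carries no effect; got '", effect, "'")
  }
  if (abs(shift) > 1) stop("shift distance must lie in [-1, 1]")
  structure(
    list(gene_id = as.character(gene_id), genotype = genotype,
         effect = effect,
         effect_params = list(shift = shift, scale = scale,
                              gain_center = gain_center,
                              gain_width = gain_width,
                              gain_amplitude = gain_amplitude)),
    class = "genotype_effect"
  )
}

# fine grid used for maxima / means of continuous patterns
.pattern_grid <- function(n = 512L) (seq_len(n) - 0.5) / n

#' Apply a genotype effect to a pattern
#'
#' Produces the perturbed pattern of a gene in a mutant genotype.
#' `loss_to_low` rescales the pattern so its maximum falls below the
#' 15 FPKM expressed floor; `uniformize` replaces the family with a uniform
#' pattern of the same embryo-wide mean (mass conserved); `shift` translates
#' the domain center / gradient origin / stripe phase by the stated fraction,
#' clipping positions to `[0, 1]`; `ectopic_gain` adds a Gaussian domain
#' term; `level_scale` multiplies amplitude and baseline.
#'
#' @param spec a [pattern_spec()].
#' @param effect a [genotype_effect()].
#' @param low_target peak FPKM after `loss_to_low` (must be < 15).
#' @return A new `pattern_spec`.
#' @export
apply_effect <- function(spec, effect, low_target = 5) {
  stopifnot(inherits(spec, "pattern_spec"), inherits(effect, "genotype_effect"))
  if (effect$genotype == "wt" && effect$effect != "none") {
    stop("wild-type patterns cannot carry an effect")
  }
  ep <- effect$effect_params
  out <- spec
  switch(effect$effect,
    none = out,
    loss_to_low = {
      stopifnot(low_target < 15)
      mx <- max(evaluate_pattern(spec, .pattern_grid()))
      if (mx > 0) {
        f <- low_target / mx
        out$params$amplitude <- spec$params$amplitude * f
        out$baseline <- spec$baseline * f
        out$extra <- lapply(spec$extra, function(t) {
          t$amplitude <- t$amplitude * f; t
        })
      }
      out
    },
    uniformize = {
      g <- .pattern_grid()
      m <- mean(evaluate_pattern(spec, g))
      out <- pattern_spec(spec$gene_id, "uniform", amplitude = m, baseline = 0)
      out
    },
    shift = {
      d <- ep$shift
      if (spec$family %in% c("anterior_domain", "posterior_domain",
                             "central_domain")) {
        out$params$center <- min(max(spec$params$center + d, 0), 1)
      } else if (spec$family %in% c("anterior_gradient",
                                    "posterior_gradient")) {
        out$params$origin <- min(max(spec$params$origin + d, 0), 1)
      } else if (spec$family == "stripes") {
        out$params$phase <- spec$params$phase + d
      }
      out$extra <- lapply(spec$extra, function(t) {
        t$center <- min(max(t$center + d, 0), 1); t
      })
      out
    },
    ectopic_gain = {
      old_center <- spec$params$center %||%
        (if (spec$family == "anterior_gradient") 0
         else if (spec$family == "posterior_gradient") 1 else 0.5)
      term <- list(
        amplitude = ep$gain_amplitude %||%
          max(spec$params$amplitude, 20),
        center = ep$gain_center %||% (if (old_center < 0.5) 0.85 else 0.15),
        width = ep$gain_width %||% 0.08
      )
      out$extra <- c(spec$extra, list(term))
      out
    },
    level_scale = {
      if (is.null(ep$scale) || ep$scale <= 0) {
        stop("level_scale requires a scale factor > 0")
      }
      out$params$amplitude <- spec$params$amplitude * ep$scale
      out$baseline <- spec$baseline * ep$scale
      out$extra <- lapply(spec$extra, function(t) {
        t$amplitude <- t$amplitude * ep$scale; t
      })
      out
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
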