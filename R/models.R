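# Internal rate-model registry shared by the fitter and the synthetic-data
# generators. Each entry knows its parameter names, the data columns it
# needs, default (data-driven) bounds, an initialisation heuristic, and how
# to evaluate the rate at a parameter vector.

pk_models <- function() {
  c("random_re", "hill", "michaelis",
    "competitive", "noncompetitive", "mixed", "uncompetitive")
}

model_spec <- function(model) {
  if (!model %in% pk_models()) {
    abort(paste0("unknown model `", model, "`; available: ",
                 paste(pk_models(), collapse = ", ")))
  }
  inh_kinds <- c("competitive", "noncompetitive", "mixed", "uncompetitive")
  if (model == "random_re") {
    list(
      params = c("vmax", "ka", "kb"),
      cols = c("a", "b", "v"),
      rate = function(d, p) rate_random_re(d$a, d$b, p["vmax"], p["ka"], p["kb"]),
      init = function(d) c(vmax = 1.2 * max(d$v), ka = median(d$a), kb = median(d$b)),
      bounds = function(d) list(
        lower = c(vmax = 0.05 * max(d$v), ka = conc_lo(d$a), kb = conc_lo(d$b)),
        upper = c(vmax = 50 * max(d$v),   ka = conc_hi(d$a), kb = conc_hi(d$b))
      ),
      check = function(d) {
        if (dplyr::n_distinct(d$a) < 2 || dplyr::n_distinct(d$b) < 2) {
          abort("non-identifiable design: the two-substrate model needs >= 2 distinct levels of both `a` and `b`")
        }
      }
    )
  } else if (model == "hill") {
    list(
      params = c("vmax", "k05", "n"),
      cols = c("s", "v"),
      rate = function(d, p) rate_hill(d$s, p["vmax"], p["k05"], p["n"]),
      init = function(d) c(vmax = 1.2 * max(d$v), k05 = median(d$s), n = 1),
      bounds = function(d) list(
        lower = c(vmax = 0.05 * max(d$v), k05 = conc_lo(d$s), n = 0.2),
        upper = c(vmax = 50 * max(d$v),   k05 = conc_hi(d$s), n = 8)
      ),
      check = function(d) {
        if (dplyr::n_distinct(d$s) < 3) {
          abort("non-identifiable design: the Hill model needs >= 3 distinct substrate levels")
        }
      }
    )
  } else if (model == "michaelis") {
    list(
      params = c("v", "km"),
      cols = c("s", "v"),
      rate = function(d, p) p["v"] * d$s / (p["km"] + d$s),
      init = function(d) c(v = 1.2 * max(d$v), km = median(d$s)),
      bounds = function(d) list(
        lower = c(v = 0.05 * max(d$v), km = conc_lo(d$s)),
        upper = c(v = 50 * max(d$v),   km = conc_hi(d$s))
      ),
      check = function(d) {
        if (dplyr::n_distinct(d$s) < 2) {
          abort("non-identifiable design: need >= 2 distinct substrate levels")
        }
      }
    )
  } else if (model %in% inh_kinds) {
    params <- c("v", "km", "ki")
    if (model == "mixed") params <- c(params, "alpha")
    list(
      params = params,
      cols = c("s", "i", "v"),
      rate = function(d, p) {
        alpha <- if (model == "mixed") p["alpha"] else 1
        rate_inhibited(d$s, d$i, p["v"], p["km"], p["ki"], alpha, kind = model)
      },
      init = function(d) {
        p <- c(v = 1.2 * max(d$v), km = median(d$s),
               ki = median(d$i[d$i > 0]))
        if (model == "mixed") p <- c(p, alpha = 1)
        p
      },
      bounds = function(d) {
        lo <- c(v = 0.05 * max(d$v), km = conc_lo(d$s), ki = conc_lo(d$i[d$i > 0]))
        hi <- c(v = 50 * max(d$v),   km = conc_hi(d$s), ki = conc_hi(d$i[d$i > 0]))
        if (model == "mixed") {
          lo <- c(lo, alpha = 0.01); hi <- c(hi, alpha = 100)
        }
        list(lower = lo, upper = hi)
      },
      check = function(d) {
        if (dplyr::n_distinct(d$s) < 2) {
          abort("non-identifiable design: need >= 2 distinct substrate levels")
        }
        if (all(d$i == 0) || dplyr::n_distinct(d$i) < 2) {
          abort("no inhibition information: need >= 2 distinct inhibitor levels")
        }
      }
    )
  }
}

conc_lo <- function(x) {
  x <- x[x > 0]
  if (!length(x)) abort("design has no positive concentrations")
  min(x) / 1e3
}

conc_hi <- function(x) {
  x <- x[x > 0]
  max(x) * 1e3
}
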