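#' Competing demographic scenario templates
#'
#' Registry of ten parametrized origin scenarios for a focal high-altitude
#' lineage (`TT`) and a derived lineage (`X`), built on a fixed deep
#' population structure: an outgroup (`CEB`) splitting deepest, a western
#' Eurasian lineage (`WEW`), and northern (`NAW`) / southern (`SAW`) wild
#' groups that diverge most recently. Keeping the deep structure fixed
#' across scenarios makes composite likelihoods comparable; only the
#' parameters of the focal lineage are free.
#'
#' The `TT` scenarios: `TT1`/`TT2` are clean splits from `NAW`/`SAW`;
#' `TT3`/`TT4` add subsequent unidirectional gene flow from the other
#' lineage, modeled as continuous migration at a per-lineage,
#' per-generation rate `m` between the founding split and the present;
#' `TT5` founds `TT` instantaneously by admixture between `NAW`
#' and `SAW` with proportion `alpha` (the `SAW` share, so `alpha = 0`
#' degenerates to a pure-`NAW` origin). The `X` scenarios take the `TT`
#' admixed origin as given: `X1` splits `X` from `TT` afterwards; `X2`
#' founds `X` by an admixture event older than `TT`'s; `X3`/`X4` split `X`
#' independently from `NAW`/`SAW` after `TT`'s founding; `X5` founds `X`
#' by an admixture event younger than `TT`'s.
#'
#' Free-parameter bounds are `Ne` in \[1e2, 1e6\], times in \[10, 1e5\]
#' generations and migration rates in \[1e-8, 1e-2\] (all searched on a
#' log10 scale), and admixture proportions in
#' \[0, 1\]; ordering constraints (e.g. a split more recent than the
#' `NAW`/`SAW` divergence) are enforced by the builder.
#'
#' @param model_id One of `"TT1"`..`"TT5"`, `"X1"`..`"X5"`.
#'
#' @return A `model_template`: list with `id`, `params` (name, lower,
#'   upper, log10 flag), `k`, `build(theta)` returning a [demog_model()],
#'   `constraints(theta)` returning violation messages, `obs_pops`, and
#'   `background` (the fixed deep-structure constants).
#' @export
#' @examples
#' tpl <- get_template("TT5")
#' tpl$params
#' m <- tpl$build(c(T_TT = 8000, Ne_TT = 5000, alpha = 0.4))
get_template <- function(model_id) {
  reg <- template_registry()
  stop_if_not(model_id %in% names(reg),
              paste0("unknown model id: ", model_id))
  reg[[model_id]]()
}

#' Fixed deep-structure constants shared by all scenario templates
#'
#' Diploid sizes, deep split times (generations) and the founding
#' parameters treated as known truth for the `X` scenarios. These are the
#' package's synthetic study conditions, not estimates.
#' @return A named list.
#' @export
scan_background <- function() {
  list(
    Ne = c(CEB = 5000, WEW = 8000, NAW = 15000, SAW = 30000),
    Ne_anc_ns = 20000,    # NAW/SAW ancestor
    Ne_anc_eur = 25000,   # + WEW ancestor
    Ne_root = 30000,      # + CEB ancestor
    T_ns = 20000, T_wew = 33000, T_ceb = 100000,
    # founding of TT taken as given in the X scenarios (fixture truth)
    T_tt = 10000, Ne_TT = 8000, alpha_tt = 0.5,
    T_x = 5000, Ne_X = 10000,
    mu = 3.6e-9, gen_time = 3
  )
}

# Event kind codes for the simulation engine and within-time priorities
# (a founding pulse precedes the accompanying split; resizes come last).
EV_SPLIT <- 0L
EV_PULSE <- 1L
EV_RESIZE <- 2L
ev_prio <- c(1, 0, 2)

# Deep background populations and rootward merge events.
base_model_parts <- function(bg, extra_pops) {
  pops <- tibble(
    name = c("CEB", "WEW", "NAW", "SAW", extra_pops$name),
    Ne = c(unname(bg$Ne[c("CEB", "WEW", "NAW", "SAW")]), extra_pops$Ne)
  )
  events <- tibble(
    time = c(bg$T_ns, bg$T_ns, bg$T_wew, bg$T_wew, bg$T_ceb, bg$T_ceb),
    kind = c("split", "resize", "split", "resize", "split", "resize"),
    pop = c("SAW", "NAW", "WEW", "NAW", "CEB", "NAW"),
    dest = c("NAW", NA, "NAW", NA, "NAW", NA),
    param = c(NA, bg$Ne_anc_ns, NA, bg$Ne_anc_eur, NA, bg$Ne_root)
  )
  list(pops = pops, events = events)
}

# Same fixed events in numeric form. Population indices (0-based):
# CEB = 0, WEW = 1, NAW = 2, SAW = 3, TT = 4, X = 5.
base_events_num <- function(bg) {
  list(time = c(bg$T_ns, bg$T_ns, bg$T_wew, bg$T_wew, bg$T_ceb, bg$T_ceb),
       kind = c(EV_SPLIT, EV_RESIZE, EV_SPLIT, EV_RESIZE, EV_SPLIT,
                EV_RESIZE),
       a = c(3L, 2L, 1L, 2L, 0L, 2L),
       b = c(2L, 0L, 2L, 0L, 2L, 0L),
       par = c(0, bg$Ne_anc_ns, 0, bg$Ne_anc_eur, 0, bg$Ne_root))
}

tt_founding_events <- function(bg) {
  tibble(
    time = c(bg$T_tt, bg$T_tt),
    kind = c("pulse", "split"),
    pop = c("TT", "TT"),
    dest = c("SAW", "NAW"),
    param = c(bg$alpha_tt, NA)
  )
}

param_row <- function(name, lower, upper, log10) {
  tibble(name = name, lower = lower, upper = upper, log10 = log10)
}
p_time <- function(name) param_row(name, 10, 1e5, TRUE)
p_ne <- function(name) param_row(name, 1e2, 1e6, TRUE)
p_alpha <- function(name) param_row(name, 0, 1, FALSE)
p_mig <- function(name) param_row(name, 1e-8, 1e-2, TRUE)

new_template <- function(id, params, build, constraints, obs_pops, bg,
                         encode_fast) {
  structure(
    list(id = id, params = params, k = nrow(params), build = build,
         constraints = constraints, obs_pops = obs_pops, background = bg,
         encode_fast = encode_fast,
         lower = params$lower, upper = params$upper,
         log10 = params$log10, par_names = params$name),
    class = "model_template"
  )
}

#' @export
print.model_template <- function(x, ...) {
  cat("<model_template> ", x$id, ": ", x$k, " free parameters (",
      paste(x$params$name, collapse = ", "), "); observed populations: ",
      paste(x$obs_pops, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Assemble a fast numeric encoding: model-specific event rows (a list of
# equal-length vectors) plus the fixed deep events, time-sorted with
# stable within-time priorities.
fast_encoder <- function(bg, n_extra_pops, Ne0_fn, extra_fn,
                         mig_fn = NULL) {
  base <- base_events_num(bg)
  pops <- c("CEB", "WEW", "NAW", "SAW", c("TT", "X")[seq_len(n_extra_pops)])
  np <- length(pops)
  zero_mig <- rep(0, np * np)
  function(theta) {
    ex <- extra_fn(theta)
    time <- c(ex$time, base$time)
    kind <- c(ex$kind, base$kind)
    o <- order(time, ev_prio[kind + 1L])
    list(Ne0 = Ne0_fn(theta),
         mig = if (is.null(mig_fn)) zero_mig else mig_fn(theta, np),
         ev_time = time[o],
         ev_kind = as.integer(kind[o]),
         ev_a = as.integer(c(ex$a, base$a)[o]),
         ev_b = as.integer(c(ex$b, base$b)[o]),
         ev_par = c(ex$par, base$par)[o],
         pops = pops)
  }
}

# Row-major migration vector with a single from -> to rate (0-based ids).
mig_single <- function(from, to) {
  function(theta, np) {
    v <- rep(0, np * np)
    v[from * np + to + 1L] <- theta[["m"]]
    v
  }
}

template_registry <- function() {
  bg <- scan_background()
  tt_obs <- c("NAW", "SAW", "TT")
  x_obs <- c("NAW", "SAW", "TT", "X")
  Ne_base <- unname(bg$Ne[c("CEB", "WEW", "NAW", "SAW")])

  tt_build <- function(extra_events_fn) {
    function(theta) {
      parts <- base_model_parts(bg, tibble(name = "TT",
                                           Ne = unname(theta[["Ne_TT"]])))
      demog_model(parts$pops, dplyr::bind_rows(extra_events_fn(theta),
                                               parts$events),
                  mu = bg$mu, gen_time = bg$gen_time)
    }
  }
  tt_build_mig <- function(extra_events_fn, from, to) {
    function(theta) {
      parts <- base_model_parts(bg, tibble(name = "TT",
                                           Ne = unname(theta[["Ne_TT"]])))
      demog_model(parts$pops, dplyr::bind_rows(extra_events_fn(theta),
                                               parts$events),
                  mu = bg$mu, gen_time = bg$gen_time,
                  migrations = tibble(from = from, to = to,
                                      rate = unname(theta[["m"]])))
    }
  }
  x_build <- function(extra_events_fn) {
    function(theta) {
      parts <- base_model_parts(
        bg, tibble(name = c("TT", "X"),
                   Ne = c(bg$Ne_TT, unname(theta[["Ne_X"]]))))
      demog_model(parts$pops,
                  dplyr::bind_rows(extra_events_fn(theta),
                                   tt_founding_events(bg), parts$events),
                  mu = bg$mu, gen_time = bg$gen_time)
    }
  }
  split_ev <- function(time, pop, dest) {
    tibble(time = time, kind = "split", pop = pop, dest = dest, param = NA)
  }
  pulse_ev <- function(time, pop, dest, a) {
    tibble(time = time, kind = "pulse", pop = pop, dest = dest, param = a)
  }
  tt_Ne0 <- function(theta) c(Ne_base, theta[["Ne_TT"]])
  x_Ne0 <- function(theta) c(Ne_base, bg$Ne_TT, theta[["Ne_X"]])
  # numeric twins of the TT founding (pulse into SAW, split into NAW)
  tt_found_num <- list(time = c(bg$T_tt, bg$T_tt),
                       kind = c(EV_PULSE, EV_SPLIT), a = c(4L, 4L),
                       b = c(3L, 2L), par = c(bg$alpha_tt, 0))
  x_extra <- function(rows) {
    list(time = c(rows$time, tt_found_num$time),
         kind = c(rows$kind, tt_found_num$kind),
         a = c(rows$a, tt_found_num$a),
         b = c(rows$b, tt_found_num$b),
         par = c(rows$par, tt_found_num$par))
  }

  list(
    TT1 = function() new_template(
      "TT1", dplyr::bind_rows(p_time("T_TT"), p_ne("Ne_TT")),
      tt_build(function(th) split_ev(th[["T_TT"]], "TT", "NAW")),
      function(th) {
        if (th[["T_TT"]] >= bg$T_ns)
          "ordering: T_TT must postdate the NAW/SAW divergence"
      },
      tt_obs, bg,
      fast_encoder(bg, 1, tt_Ne0, function(th) {
        list(time = th[["T_TT"]], kind = EV_SPLIT, a = 4L, b = 2L, par = 0)
      })),
    TT2 = function() new_template(
      "TT2", dplyr::bind_rows(p_time("T_TT"), p_ne("Ne_TT")),
      tt_build(function(th) split_ev(th[["T_TT"]], "TT", "SAW")),
      function(th) {
        if (th[["T_TT"]] >= bg$T_ns)
          "ordering: T_TT must postdate the NAW/SAW divergence"
      },
      tt_obs, bg,
      fast_encoder(bg, 1, tt_Ne0, function(th) {
        list(time = th[["T_TT"]], kind = EV_SPLIT, a = 4L, b = 3L, par = 0)
      })),
    TT3 = function() new_template(
      "TT3", dplyr::bind_rows(p_time("T_TT"), p_ne("Ne_TT"), p_mig("m")),
      tt_build_mig(function(th) split_ev(th[["T_TT"]], "TT", "NAW"),
                   from = "TT", to = "SAW"),
      function(th) {
        if (th[["T_TT"]] >= bg$T_ns)
          "ordering: T_TT must postdate the NAW/SAW divergence"
      },
      tt_obs, bg,
      fast_encoder(bg, 1, tt_Ne0, function(th) {
        list(time = th[["T_TT"]], kind = EV_SPLIT, a = 4L, b = 2L, par = 0)
      }, mig_single(4L, 3L))),
    TT4 = function() new_template(
      "TT4", dplyr::bind_rows(p_time("T_TT"), p_ne("Ne_TT"), p_mig("m")),
      tt_build_mig(function(th) split_ev(th[["T_TT"]], "TT", "SAW"),
                   from = "TT", to = "NAW"),
      function(th) {
        if (th[["T_TT"]] >= bg$T_ns)
          "ordering: T_TT must postdate the NAW/SAW divergence"
      },
      tt_obs, bg,
      fast_encoder(bg, 1, tt_Ne0, function(th) {
        list(time = th[["T_TT"]], kind = EV_SPLIT, a = 4L, b = 3L, par = 0)
      }, mig_single(4L, 2L))),
    TT5 = function() new_template(
      "TT5", dplyr::bind_rows(p_time("T_TT"), p_ne("Ne_TT"),
                              p_alpha("alpha")),
      tt_build(function(th) dplyr::bind_rows(
        pulse_ev(th[["T_TT"]], "TT", "SAW", th[["alpha"]]),
        split_ev(th[["T_TT"]], "TT", "NAW"))),
      function(th) {
        if (th[["T_TT"]] >= bg$T_ns)
          "ordering: T_TT must postdate the NAW/SAW divergence"
      },
      tt_obs, bg,
      fast_encoder(bg, 1, tt_Ne0, function(th) {
        list(time = c(th[["T_TT"]], th[["T_TT"]]),
             kind = c(EV_PULSE, EV_SPLIT), a = c(4L, 4L), b = c(3L, 2L),
             par = c(th[["alpha"]], 0))
      })),
    X1 = function() new_template(
      "X1", dplyr::bind_rows(p_time("T_X"), p_ne("Ne_X")),
      x_build(function(th) split_ev(th[["T_X"]], "X", "TT")),
      function(th) {
        if (th[["T_X"]] >= bg$T_tt)
          "ordering: T_X must postdate the founding of TT"
      },
      x_obs, bg,
      fast_encoder(bg, 2, x_Ne0, function(th) x_extra(
        list(time = th[["T_X"]], kind = EV_SPLIT, a = 5L, b = 4L,
             par = 0)))),
    X2 = function() new_template(
      "X2", dplyr::bind_rows(p_time("T_X"), p_ne("Ne_X"),
                             p_alpha("alpha_X")),
      x_build(function(th) dplyr::bind_rows(
        pulse_ev(th[["T_X"]], "X", "SAW", th[["alpha_X"]]),
        split_ev(th[["T_X"]], "X", "NAW"))),
      function(th) {
        c(if (th[["T_X"]] <= bg$T_tt)
            "ordering: X's admixture must predate the founding of TT",
          if (th[["T_X"]] >= bg$T_ns)
            "ordering: T_X must postdate the NAW/SAW divergence")
      },
      x_obs, bg,
      fast_encoder(bg, 2, x_Ne0, function(th) x_extra(
        list(time = c(th[["T_X"]], th[["T_X"]]),
             kind = c(EV_PULSE, EV_SPLIT), a = c(5L, 5L), b = c(3L, 2L),
             par = c(th[["alpha_X"]], 0))))),
    X3 = function() new_template(
      "X3", dplyr::bind_rows(p_time("T_X"), p_ne("Ne_X")),
      x_build(function(th) split_ev(th[["T_X"]], "X", "NAW")),
      function(th) {
        if (th[["T_X"]] >= bg$T_tt)
          "ordering: T_X must postdate the founding of TT"
      },
      x_obs, bg,
      fast_encoder(bg, 2, x_Ne0, function(th) x_extra(
        list(time = th[["T_X"]], kind = EV_SPLIT, a = 5L, b = 2L,
             par = 0)))),
    X4 = function() new_template(
      "X4", dplyr::bind_rows(p_time("T_X"), p_ne("Ne_X")),
      x_build(function(th) split_ev(th[["T_X"]], "X", "SAW")),
      function(th) {
        if (th[["T_X"]] >= bg$T_tt)
          "ordering: T_X must postdate the founding of TT"
      },
      x_obs, bg,
      fast_encoder(bg, 2, x_Ne0, function(th) x_extra(
        list(time = th[["T_X"]], kind = EV_SPLIT, a = 5L, b = 3L,
             par = 0)))),
    X5 = function() new_template(
      "X5", dplyr::bind_rows(p_time("T_X"), p_ne("Ne_X"),
                             p_alpha("alpha_X")),
      x_build(function(th) dplyr::bind_rows(
        pulse_ev(th[["T_X"]], "X", "SAW", th[["alpha_X"]]),
        split_ev(th[["T_X"]], "X", "NAW"))),
      function(th) {
        if (th[["T_X"]] >= bg$T_tt)
          "ordering: X's admixture must postdate the founding of TT"
      },
      x_obs, bg,
      fast_encoder(bg, 2, x_Ne0, function(th) x_extra(
        list(time = c(th[["T_X"]], th[["T_X"]]),
             kind = c(EV_PULSE, EV_SPLIT), a = c(5L, 5L), b = c(3L, 2L),
             par = c(th[["alpha_X"]], 0)))))
  )
}

#' List available scenario templates
#' @return Character vector of model ids.
#' @export
list_templates <- function() names(template_registry())

# Cheap violation check used in optimization hot paths; returns a
# character vector of messages (empty when valid).
check_theta <- function(template, theta) {
  out <- character()
  bad <- is.na(theta) | theta < template$lower | theta > template$upper
  if (any(bad)) {
    out <- sprintf("%s = %g outside [%g, %g]",
                   template$par_names[bad], theta[bad],
                   template$lower[bad], template$upper[bad])
    return(out)  # skip ordering checks on out-of-bounds input
  }
  v <- template$constraints(as.list(setNames(theta, template$par_names)))
  c(out, unlist(v))
}

#' Validate a parameter vector against a template
#'
#' Checks bounds and ordering constraints; violations are reported, not
#' thrown.
#'
#' @param template A `model_template` from [get_template()].
#' @param theta Named numeric vector of length `template$k`.
#' @return A tibble with columns `rule` and `message`; zero rows when the
#'   vector is valid.
#' @export
#' @examples
#' tpl <- get_template("TT5")
#' validate_parameters(tpl, c(T_TT = 8000, Ne_TT = 5000, alpha = 1.2))
validate_parameters <- function(template, theta) {
  stop_if_not(length(theta) == template$k,
              "parameter vector length must equal template$k")
  if (!is.null(names(theta))) theta <- theta[template$par_names]
  msgs <- check_theta(template, unname(theta))
  tibble(rule = ifelse(grepl("^ordering", msgs), "ordering", "bounds"),
         message = msgs)
}

# TRUE when theta is inside bounds and satisfies ordering constraints.
params_valid <- function(template, theta) {
  if (!is.null(names(theta))) theta <- theta[template$par_names]
  length(check_theta(template, unname(theta))) == 0
}

# Draw a random in-bounds, constraint-satisfying start (log-uniform for
# log-scale parameters).
sample_start <- function(template, max_tries = 1000) {
  lo <- ifelse(template$log10, log10(template$lower), template$lower)
  hi <- ifelse(template$log10, log10(template$upper), template$upper)
  for (i in seq_len(max_tries)) {
    z <- stats::runif(template$k, lo, hi)
    th <- ifelse(template$log10, 10^z, z)
    names(th) <- template$par_names
    if (params_valid(template, th)) return(th)
  }
  rlang::abort("could not draw a valid random start")
}
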