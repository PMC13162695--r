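#' Demographic models
#'
#' A demographic model is a set of populations with diploid effective sizes
#' plus a time-ordered list of events, read backward in time:
#' `split` moves all lineages of a derived population into its ancestor,
#' `pulse` moves each lineage of a recipient to a donor with probability
#' `param` (an instantaneous admixture pulse with proportion `param`), and
#' `resize` changes a population's diploid size to `param`.
#' Times are in generations before present; `mu` is the mutation rate per
#' site per generation and `gen_time` (years) is carried for reporting only.
#'
#' @param populations A data frame with columns `name` and `Ne`
#'   (diploid effective size, > 0).
#' @param events A data frame with columns `time` (generations, >= 0),
#'   `kind` (one of `"split"`, `"pulse"`, `"resize"`), `pop` (the population
#'   acted on), `dest` (ancestor for `split`, donor for `pulse`, `NA` for
#'   `resize`) and `param` (admixture proportion in \[0, 1\] for `pulse`, the
#'   new Ne for `resize`, ignored for `split`).
#' @param mu Mutation rate per site per generation.
#' @param gen_time Years per generation (reporting only).
#' @param migrations Optional data frame with columns `from`, `to`, `rate`:
#'   continuous unidirectional migration, expressed backward in time as the
#'   per-lineage, per-generation rate at which a lineage in `from` jumps to
#'   `to`, active from the present until changed by a `"migration"` event
#'   (an event with `kind = "migration"` sets the `pop` -> `dest` rate to
#'   `param` from its `time` rootward).
#'
#' @return An object of class `demog_model`.
#' @export
#' @examples
#' m <- demog_model(
#'   populations = data.frame(name = c("A", "B"), Ne = c(1e4, 1e4)),
#'   events = data.frame(time = 5000, kind = "split",
#'                       pop = "B", dest = "A", param = NA)
#' )
#' m
demog_model <- function(populations, events = NULL,
                        mu = 3.6e-9, gen_time = 3, migrations = NULL) {
  populations <- tibble::as_tibble(populations)
  stop_if_not(all(c("name", "Ne") %in% names(populations)),
              "`populations` needs columns `name` and `Ne`")
  stop_if_not(!anyDuplicated(populations$name), "duplicated population names")
  stop_if_not(all(populations$Ne > 0), "all Ne must be > 0")
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(time = double(), kind = character(), pop = character(),
                     dest = character(), param = double())
  } else {
    events <- tibble::as_tibble(events)
    if (!"dest" %in% names(events)) events$dest <- NA_character_
    if (!"param" %in% names(events)) events$param <- NA_real_
    events <- events[order(events$time), ]
  }
  stop_if_not(all(events$time >= 0), "event times must be >= 0")
  stop_if_not(all(events$kind %in% c("split", "pulse", "resize",
                                     "migration")),
              "unknown event kind")
  stop_if_not(all(events$pop %in% populations$name),
              "event population not in model")
  need_dest <- events$kind %in% c("split", "pulse", "migration")
  stop_if_not(all(events$dest[need_dest] %in% populations$name),
              "event destination not in model")
  pulses <- events$kind == "pulse"
  stop_if_not(all(events$param[pulses] >= 0 & events$param[pulses] <= 1),
              "admixture proportions must lie in [0, 1]")
  resz <- events$kind == "resize"
  stop_if_not(all(events$param[resz] > 0), "resize Ne must be > 0")
  mig_ev <- events$kind == "migration"
  stop_if_not(all(events$param[mig_ev] >= 0),
              "migration rates must be >= 0")
  if (is.null(migrations) || nrow(migrations) == 0) {
    migrations <- tibble(from = character(), to = character(),
                         rate = double())
  } else {
    migrations <- tibble::as_tibble(migrations)
    stop_if_not(all(c("from", "to", "rate") %in% names(migrations)),
                "`migrations` needs columns from, to, rate")
    stop_if_not(all(migrations$from %in% populations$name) &&
                  all(migrations$to %in% populations$name),
                "migration population not in model")
    stop_if_not(all(migrations$rate >= 0), "migration rates must be >= 0")
  }
  m <- structure(
    list(populations = populations, events = events,
         migrations = migrations, mu = mu, gen_time = gen_time),
    class = "demog_model"
  )
  check_single_ancestor(m)
  m
}

# Following all splits rootward, exactly one population must remain active.
check_single_ancestor <- function(m) {
  active <- m$populations$name
  ev <- m$events
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "split") {
      stop_if_not(ev$pop[i] %in% active,
                  sprintf("population %s splits twice", ev$pop[i]))
      stop_if_not(ev$dest[i] %in% active,
                  sprintf("split destination %s is no longer active", ev$dest[i]))
      active <- setdiff(active, ev$pop[i])
    } else if (ev$kind[i] == "pulse") {
      stop_if_not(ev$pop[i] %in% active && ev$dest[i] %in% active,
                  "pulse involves an inactive population")
    }
  }
  stop_if_not(length(active) == 1,
              "model must end in a single ancestral population")
  invisible(TRUE)
}

#' @export
print.demog_model <- function(x, ...) {
  cat("<demog_model> ", nrow(x$populations), " populations, ",
      nrow(x$events), " events, mu = ", format(x$mu),
      ", generation time = ", x$gen_time, " y\n", sep = "")
  print(x$populations)
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

# Encode a model for the C++ engine: 0-based population indices, event kind
# codes 0 = split, 1 = pulse, 2 = resize, 3 = migration-rate change. Ties
# in time keep data order (pulse-then-split founding events rely on this).
encode_model <- function(m) {
  pops <- m$populations$name
  np <- length(pops)
  ev <- m$events
  kind <- match(ev$kind, c("split", "pulse", "resize", "migration")) - 1L
  mig <- matrix(0, np, np)
  mg <- m$migrations
  if (!is.null(mg) && nrow(mg) > 0) {
    for (i in seq_len(nrow(mg))) {
      mig[match(mg$from[i], pops), match(mg$to[i], pops)] <- mg$rate[i]
    }
  }
  list(
    Ne0 = as.double(m$populations$Ne),
    # engine layout is row-major (rate[from * npop + to])
    mig = as.double(t(mig)),
    ev_time = as.double(ev$time),
    ev_kind = as.integer(kind),
    ev_a = as.integer(match(ev$pop, pops) - 1L),
    ev_b = {
      b <- match(ev$dest, pops) - 1L
      b[is.na(b)] <- 0L
      as.integer(b)
    },
    ev_par = {
      p <- as.double(ev$param)
      p[is.na(p)] <- 0
      p
    },
    pops = pops
  )
}
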