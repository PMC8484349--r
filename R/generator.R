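#' Experimental scenario specification
#'
#' Describes one oviposition experiment arm: how many founder females and
#' which host eggs each is offered. The built-in names reproduce the study
#' designs: three no-choice arms (12 native eggs on the usual plant, the
#' fictitious plant, or filter paper; 20 founders each), a choice arm (4
#' native eggs on each of the three substrates simultaneously; 20 founders),
#' and the fictitious-host experiment arms (6 native + 6 fictitious eggs on
#' the fictitious plant, 15 founders; 6 native on the usual plant, 11
#' founders; 12 native on the usual plant, 19 founders).
#'
#' @param name Scenario label; one of the built-ins (see Details) or any
#'   label when \code{hosts_offered} is supplied explicitly.
#' @param n_founders Number of founder females; defaults to the built-in
#'   design's group size.
#' @param hosts_offered data.frame with columns \code{substrate},
#'   \code{host_species}, \code{count}; defaults to the built-in design.
#' @param exposure Nominal exposure duration label (metadata only).
#' @return A \code{scenario_spec} object.
#' @export
#' @examples
#' scenario_spec("choice")
scenario_spec <- function(name, n_founders = NULL, hosts_offered = NULL,
                          exposure = "8h") {
  builtin <- builtin_scenarios()
  if (is.null(hosts_offered)) {
    if (!name %in% names(builtin))
      stop("unknown scenario '", name, "'; built-ins: ",
           paste(names(builtin), collapse = ", "),
           " (or supply `hosts_offered`)", call. = FALSE)
    hosts_offered <- builtin[[name]]$hosts
    if (is.null(n_founders)) n_founders <- builtin[[name]]$n_founders
  }
  if (is.null(n_founders)) stop("`n_founders` required", call. = FALSE)
  stopifnot(is.data.frame(hosts_offered),
            all(c("substrate", "host_species", "count") %in%
                  names(hosts_offered)))
  if (sum(hosts_offered$count) <= 0)
    stop("total hosts per founder must be > 0", call. = FALSE)
  structure(list(name = name, n_founders = as.integer(n_founders),
                 hosts_offered = hosts_offered, exposure = exposure),
            class = "scenario_spec")
}

#' Built-in study scenario designs
#'
#' @return Named list: for each built-in scenario, its default founder count
#'   and offered-host design table.
#' @export
builtin_scenarios <- function() {
  h <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(substrate = m[, 1], host_species = m[, 2],
               count = as.integer(m[, 3]))
  }
  list(
    no_choice_usual     = list(n_founders = 20L,
      hosts = h("usual_plant", "native", 12)),
    no_choice_fictplant = list(n_founders = 20L,
      hosts = h("fictitious_plant", "native", 12)),
    no_choice_control   = list(n_founders = 20L,
      hosts = h("control_paper", "native", 12)),
    choice              = list(n_founders = 20L,
      hosts = h("usual_plant", "native", 4,
                "fictitious_plant", "native", 4,
                "control_paper", "native", 4)),
    fict_host_mix       = list(n_founders = 15L,
      hosts = h("fictitious_plant", "native", 6,
                "fictitious_plant", "fictitious", 6)),
    low_density         = list(n_founders = 11L,
      hosts = h("usual_plant", "native", 6)),
    high_density        = list(n_founders = 19L,
      hosts = h("usual_plant", "native", 12))
  )
}

#' Default synthetic clutch-size distribution
#'
#' A plausible clutch-size frequency profile with its mode at 2-3
#' offspring. It is a synthetic stand-in: the observed frequency tables are
#' not publicly deposited, so these weights are a package default, clearly
#' not measured data. Supply observed tables via [read_clutch_freqs()]
#' where available.
#'
#' @param max_clutch Support bound (default 7).
#' @return A [clutch_dist()].
#' @export
default_clutch_dist <- function(max_clutch = 7L) {
  clutch_dist(c(`1` = 10, `2` = 24, `3` = 22, `4` = 12, `5` = 6,
                `6` = 3, `7` = 1), max_clutch = max_clutch)
}

#' Generator parameters
#'
#' Stochastic mechanism of the synthetic experiment generator. Parasitism is
#' Bernoulli per offered egg with a substrate-by-host-species probability on
#' the logit scale plus a founder-level (Petri-dish) Normal random intercept
#' — the overdispersion structure that the dish random factor in the mixed
#' models is designed to capture. Clutch sizes are drawn per parasitized egg
#' from the substrate's clutch-size distribution, truncated and renormalised
#' to the founder's remaining egg budget (females are pro-ovigenic: a fixed
#' egg complement). Sexes are binomial at \code{p_female}. Offspring in
#' fictitious hosts never emerge; the host beetle's own emergence from a
#' fictitious egg is an independent Bernoulli: 0.22 if parasitized, 0.94 if
#' not (the untouched-control rate).
#'
#' @param p_parasitize Named list or single number: per-substrate (optionally
#'   \code{substrate.host_species}) parasitism probability. A single number
#'   applies everywhere.
#' @param clutch_dist A [clutch_dist()] or named list of them by substrate.
#' @param p_female Female proportion (default 0.25: 3:1 male:female).
#' @param dish_sd SD of the founder-level random intercept on the parasitism
#'   logit (default 0.5).
#' @param egg_budget Maximum eggs a founder can lay (default 32; a package
#'   default, configurable).
#' @param p_host_emerge_parasitized_fict Host-beetle emergence probability
#'   for parasitized fictitious eggs (default 0.22).
#' @param p_host_emerge_control_fict Emergence probability for unparasitized
#'   fictitious eggs (default 0.94).
#' @param max_clutch Clutch-size support bound (default 7).
#' @return A \code{generator_params} object.
#' @export
generator_params <- function(p_parasitize = 0.7,
                             clutch_dist = default_clutch_dist(),
                             p_female = 0.25,
                             dish_sd = 0.5,
                             egg_budget = 32L,
                             p_host_emerge_parasitized_fict = 0.22,
                             p_host_emerge_control_fict = 0.94,
                             max_clutch = 7L) {
  probs <- c(p_female, p_host_emerge_parasitized_fict,
             p_host_emerge_control_fict,
             unlist(p_parasitize, use.names = FALSE))
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (dish_sd < 0) stop("`dish_sd` must be >= 0", call. = FALSE)
  egg_budget <- as.integer(egg_budget)
  if (is.na(egg_budget) || egg_budget < 1L)
    stop("`egg_budget` must be >= 1", call. = FALSE)
  if (egg_budget < max_clutch)
    stop("`egg_budget` must be >= max_clutch", call. = FALSE)
  structure(list(
    p_parasitize = p_parasitize, clutch_dist = clutch_dist,
    p_female = p_female, dish_sd = dish_sd, egg_budget = egg_budget,
    p_host_emerge_parasitized_fict = p_host_emerge_parasitized_fict,
    p_host_emerge_control_fict = p_host_emerge_control_fict,
    max_clutch = as.integer(max_clutch)), class = "generator_params")
}

lookup_p_parasitize <- function(params, substrate, host_species) {
  p <- params$p_parasitize
  if (is.numeric(p) && length(p) == 1L && is.null(names(p)))
    return(rep(p, length(substrate)))
  key_full <- paste(substrate, host_species, sep = ".")
  vapply(seq_along(substrate), function(i) {
    if (!is.null(p[[key_full[i]]])) return(p[[key_full[i]]])
    if (!is.null(p[[substrate[i]]])) return(p[[substrate[i]]])
    stop("no parasitism probability configured for substrate '",
         substrate[i], "' (host ", host_species[i], ")", call. = FALSE)
  }, numeric(1))
}

lookup_clutch_dist <- function(params, substrate) {
  cd <- params$clutch_dist
  if (inherits(cd, "clutch_dist")) return(cd)
  if (!is.null(cd[[substrate]])) return(cd[[substrate]])
  stop("no clutch distribution configured for substrate '", substrate, "'",
       call. = FALSE)
}

# draw one clutch size from dist truncated to `cap` and renormalised
draw_truncated_clutch <- function(dist, cap) {
  cap <- min(cap, dist$max_clutch)
  p <- dist$p[seq_len(cap)]
  if (sum(p) <= 0) p <- rep(1, cap)   # degenerate tail: uniform fallback
  sample.int(cap, 1L, prob = p)
}

#' Simulate an oviposition experiment
#'
#' Generates a tidy host-egg table (see [host_egg_schema]) for one scenario
#' under a [generator_params()] mechanism. Reproducible: identical
#' \code{(spec, params, seed)} give identical tables.
#'
#' @param spec A [scenario_spec()].
#' @param params A [generator_params()].
#' @param seed Integer seed.
#' @return Host-egg data.frame with the extra column
#'   \code{host_beetle_emerged} (NA for native hosts).
#' @export
#' @examples
#' tab <- generate_trials(scenario_spec("low_density"),
#'                        generator_params(), seed = 1)
#' head(tab)
generate_trials <- function(spec, params, seed) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(params, "generator_params"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  offered <- spec$hosts_offered
  substrate <- rep(offered$substrate, offered$count)
  host_species <- rep(offered$host_species, offered$count)
  n_hosts <- length(substrate)
  p_base <- lookup_p_parasitize(params, substrate, host_species)

  rows <- vector("list", spec$n_founders)
  for (f in seq_len(spec$n_founders)) {
    intercept <- stats::rnorm(1L, 0, params$dish_sd)
    p_f <- stats::plogis(stats::qlogis(pmin(pmax(p_base, 1e-12),
                                            1 - 1e-12)) + intercept)
    # exact-zero / exact-one probabilities stay exact
    p_f[p_base == 0] <- 0
    p_f[p_base == 1] <- 1
    budget <- params$egg_budget
    parasitized <- logical(n_hosts)
    clutch <- rep(NA_integer_, n_hosts)
    fem <- rep(NA_integer_, n_hosts)
    for (i in seq_len(n_hosts)) {
      if (budget < 1L) break
      if (stats::runif(1L) < p_f[i]) {
        d <- lookup_clutch_dist(params, substrate[i])
        s <- draw_truncated_clutch(d, budget)
        parasitized[i] <- TRUE
        clutch[i] <- s
        fem[i] <- stats::rbinom(1L, s, params$p_female)
        budget <- budget - s
      }
    }
    hb <- rep(NA, n_hosts)
    fict <- host_species == "fictitious"
    if (any(fict)) {
      pr <- ifelse(parasitized[fict],
                   params$p_host_emerge_parasitized_fict,
                   params$p_host_emerge_control_fict)
      hb[fict] <- stats::runif(sum(fict)) < pr
    }
    rows[[f]] <- data.frame(
      founder_id = sprintf("%s_%03d", spec$name, f),
      group = spec$name,
      substrate = substrate,
      host_species = host_species,
      parasitized = parasitized,
      clutch_size = clutch,
      n_females = fem,
      emerged = parasitized & host_species == "native",
      host_beetle_emerged = hb
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_host_table(out)
}

#' Method-of-moments recovery of generator parameters
#'
#' Self-validation of the generator: estimates the per-cell parasitism
#' probability (with Clopper-Pearson 95% CI), the per-substrate mean clutch
#' size (t-based 95% CI), and the female proportion (Clopper-Pearson 95%
#' CI) from a tidy host-egg table.
#'
#' @param tab Host-egg table.
#' @return List with data.frames \code{p_parasitize} (one row per
#'   substrate-by-host-species cell; zero-exposure cells absent),
#'   \code{clutch_mean} and one-row \code{p_female}.
#' @export
recover_params <- function(tab) {
  validate_host_table(tab)
  if (nrow(tab) == 0L) stop("empty table", call. = FALSE)
  cells <- split(tab, paste(tab$substrate, tab$host_species, sep = "."))
  p_par <- do.call(rbind, lapply(cells, function(cl) {
    n <- nrow(cl); x <- sum(cl$parasitized)
    ci <- interval_95(c(x, n), family = "binomial")
    data.frame(substrate = cl$substrate[1L],
               host_species = cl$host_species[1L],
               n = n, estimate = x / n, lower = ci[1L], upper = ci[2L])
  }))
  rownames(p_par) <- NULL
  par_tab <- tab[tab$parasitized, , drop = FALSE]
  clutch_mean <- if (nrow(par_tab) > 0) {
    do.call(rbind, lapply(split(par_tab, par_tab$substrate), function(cl) {
      ci <- interval_95(cl$clutch_size, family = "gaussian")
      data.frame(substrate = cl$substrate[1L], n = nrow(cl),
                 estimate = mean(cl$clutch_size),
                 lower = ci[1L], upper = ci[2L])
    }))
  } else NULL
  if (!is.null(clutch_mean)) rownames(clutch_mean) <- NULL
  tot_off <- sum(par_tab$clutch_size)
  tot_fem <- sum(par_tab$n_females)
  p_female <- if (tot_off > 0) {
    ci <- interval_95(c(tot_fem, tot_off), family = "binomial")
    data.frame(n_offspring = tot_off, estimate = tot_fem / tot_off,
               lower = ci[1L], upper = ci[2L])
  } else NULL
  list(p_parasitize = p_par, clutch_mean = clutch_mean, p_female = p_female)
}
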