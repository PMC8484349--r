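# shared fixture builders: small host-egg tables assembled in code

host_rows <- function(founder_id, group, clutch_sizes, n_females,
                      host_species = "native", substrate = "usual_plant",
                      n_unparasitized = 0) {
  par <- data.frame(
    founder_id = founder_id, group = group, substrate = substrate,
    host_species = host_species, parasitized = TRUE,
    clutch_size = as.integer(clutch_sizes),
    n_females = as.integer(n_females),
    emerged = host_species == "native"
  )
  if (n_unparasitized > 0) {
    par <- rbind(par, data.frame(
      founder_id = founder_id, group = group, substrate = substrate,
      host_species = host_species, parasitized = FALSE,
      clutch_size = NA_integer_, n_females = NA_integer_, emerged = FALSE))
  }
  par
}

# two-arm no-choice design: n_per_arm founders each offered `eggs` native
# hosts on one of two substrates
two_arm_spec <- function(substrates = c("usual_plant", "fictitious_plant"),
                         eggs = 12L) {
  lapply(substrates, function(s)
    scenario_spec(paste0("arm_", s), n_founders = 10L,
                  hosts_offered = data.frame(substrate = s,
                                             host_species = "native",
                                             count = eggs)))
}

simulate_two_arm <- function(p = c(0.5, 0.5), seed = 1, dish_sd = 0,
                             n_per_arm = 10L, eggs = 12L) {
  substrates <- c("usual_plant", "fictitious_plant")
  tabs <- lapply(seq_along(substrates), function(i) {
    sp <- scenario_spec(paste0("arm_", i), n_founders = n_per_arm,
                        hosts_offered = data.frame(
                          substrate = substrates[i],
                          host_species = "native", count = eggs))
    params <- generator_params(p_parasitize = p[i], dish_sd = dish_sd,
                               egg_budget = 100)
    tb <- generate_trials(sp, params, seed = seed * 1000 + i)
    tb$founder_id <- paste0(substrates[i], "_", tb$founder_id)
    tb
  })
  do.call(rbind, tabs)
}

# brute-force enumeration of feasible clutch-size multisets and their
# distribution-induced weights (independent oracle for allocation)
enumerate_feasible_multisets <- function(total, n_hosts, p) {
  mc <- length(p)
  res <- list()
  recurse <- function(remaining, max_size, parts) {
    if (remaining == 0) {
      res[[length(res) + 1L]] <<- parts
      return(invisible())
    }
    if (length(parts) >= n_hosts) return(invisible())
    for (s in seq_len(min(max_size, remaining))) {
      recurse(remaining - s, s, c(parts, s))
    }
  }
  recurse(total, mc, integer(0))
  if (length(res) == 0) return(NULL)
  weights <- vapply(res, function(parts) {
    k <- length(parts)
    counts <- tabulate(parts, nbins = mc)
    # multiset weight: number of orderings times product of probabilities
    exp(lfactorial(k) - sum(lfactorial(counts))) * prod(p[parts])
  }, numeric(1))
  list(multisets = res, weights = weights / sum(weights))
}

multiset_key <- function(sizes) paste(sort(sizes), collapse = "-")
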