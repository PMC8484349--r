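#' Empirical clutch-size frequency distribution
#'
#' Holds non-negative frequencies over clutch sizes \code{1..max_clutch},
#' normalised to probabilities. These drive how a female's offspring are
#' distributed over host eggs; in practice they come from observed
#' clutch-size frequency tables.
#'
#' @param weights Non-negative numeric vector of frequencies; either named
#'   by clutch size or positional over \code{1..length(weights)}.
#' @param max_clutch Support upper bound; defaults to the largest size with
#'   a weight supplied.
#' @return A \code{clutch_dist} object: probabilities over \code{1..max_clutch}.
#' @export
#' @examples
#' clutch_dist(c(`1` = 5, `2` = 10, `3` = 8, `4` = 3))
clutch_dist <- function(weights, max_clutch = NULL) {
  if (!is.numeric(weights) || length(weights) == 0L)
    stop("`weights` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("`weights` must be finite and non-negative", call. = FALSE)
  sizes <- if (!is.null(names(weights))) as.integer(names(weights))
           else seq_along(weights)
  if (any(is.na(sizes)) || any(sizes < 1L))
    stop("clutch sizes must be integers >= 1", call. = FALSE)
  if (anyDuplicated(sizes)) stop("duplicated clutch sizes", call. = FALSE)
  if (is.null(max_clutch)) max_clutch <- max(sizes)
  max_clutch <- as.integer(max_clutch)
  if (any(sizes > max_clutch))
    stop("weights supplied beyond max_clutch", call. = FALSE)
  p <- numeric(max_clutch)
  p[sizes] <- weights
  tot <- sum(p)
  if (tot <= 0) stop("at least one weight must be positive", call. = FALSE)
  structure(list(p = p / tot, max_clutch = max_clutch), class = "clutch_dist")
}

#' @export
print.clutch_dist <- function(x, ...) {
  cat("Clutch-size distribution on 1..", x$max_clutch, "\n", sep = "")
  print(stats::setNames(round(x$p, 4), seq_len(x$max_clutch)))
  invisible(x)
}

dist_mean <- function(dist) sum(seq_len(dist$max_clutch) * dist$p)

#' Read a clutch-size frequency table from CSV
#'
#' Expects columns \code{size} and \code{freq} (one row per clutch size).
#' User-supplied observed frequency tables enter the pipeline through this
#' loader.
#'
#' @param path Path to a CSV file.
#' @param max_clutch Optional support upper bound.
#' @return A [clutch_dist()].
#' @export
read_clutch_freqs <- function(path, max_clutch = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("size", "freq")
  if (!all(need %in% names(tab)))
    stop("frequency table must have columns 'size' and 'freq'; missing: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  clutch_dist(stats::setNames(tab$freq, tab$size), max_clutch = max_clutch)
}

#' Distribute a fixed number of offspring over host eggs
#'
#' Splits \code{total_offspring} into clutches of sizes drawn from (or
#' matched in expectation to) a clutch-size distribution, using at most
#' \code{n_hosts} host eggs.
#'
#' Two modes:
#' \describe{
#'   \item{\code{"expected"}}{Deterministic. Target clutch counts per size
#'     are the frequency-proportional expectations rounded by the
#'     largest-remainder method, then repaired to exact feasibility: while
#'     the allocation over-shoots the total, the largest clutch is shrunk by
#'     one; while it under-shoots, the smallest clutch below
#'     \code{max_clutch} is grown by one (adding a new clutch of 1 when no
#'     host is over-full and hosts remain). If more hosts are used than are
#'     available, the two smallest clutches are merged. All steps are
#'     deterministic, so repeated calls are identical.}
#'   \item{\code{"sampled"}}{Stochastic. Clutch sizes are drawn i.i.d. from
#'     the distribution; a draw sequence is accepted only if it sums exactly
#'     to the total using at most \code{n_hosts} hosts (rejection sampling),
#'     so each feasible multiset appears with probability proportional to
#'     its distribution-induced weight. After \code{max_attempts} rejections
#'     the deterministic expected-mode allocation is returned with a
#'     warning.}
#' }
#'
#' @param total_offspring Total offspring to place (>= 0).
#' @param n_hosts Number of host eggs available.
#' @param dist A [clutch_dist()].
#' @param mode \code{"expected"} or \code{"sampled"}.
#' @param seed Optional integer seed for sampled mode; without one the
#'   current RNG stream is used and the drawn seed is reported via a message.
#' @param max_attempts Rejection bound for sampled mode.
#' @return Integer vector of clutch sizes (possibly empty), summing to
#'   \code{total_offspring}, each in \code{1..dist$max_clutch}.
#' @export
#' @examples
#' d <- clutch_dist(c(`3` = 1, `4` = 1))
#' sort(allocate_offspring(7, 2, d, mode = "expected"))  # 3 4
allocate_offspring <- function(total_offspring, n_hosts, dist,
                               mode = c("expected", "sampled"),
                               seed = NULL, max_attempts = 10000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dist, "clutch_dist"))
  total_offspring <- as.integer(total_offspring)
  n_hosts <- as.integer(n_hosts)
  if (is.na(total_offspring) || total_offspring < 0L)
    stop("`total_offspring` must be >= 0", call. = FALSE)
  if (is.na(n_hosts) || n_hosts < 0L)
    stop("`n_hosts` must be >= 0", call. = FALSE)
  mc <- dist$max_clutch
  if (total_offspring > n_hosts * mc)
    stop("infeasible: ", total_offspring, " offspring cannot fit in ",
         n_hosts, " hosts at max clutch ", mc, call. = FALSE)
  if (total_offspring == 0L) return(integer(0))

  if (mode == "expected")
    return(allocate_expected(total_offspring, n_hosts, dist))

  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message("sampled-mode allocation drew seed ", seed)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sizes <- seq_len(mc)
  for (a in seq_len(max_attempts)) {
    draw <- integer(0)
    remaining <- total_offspring
    ok <- TRUE
    while (remaining > 0L) {
      if (length(draw) >= n_hosts) { ok <- FALSE; break }
      s <- sample(sizes, 1L, prob = dist$p)
      if (s > remaining) { ok <- FALSE; break }
      draw <- c(draw, s)
      remaining <- remaining - s
    }
    if (ok) return(draw)
  }
  warning("sampled allocation exceeded ", max_attempts,
          " attempts; falling back to expected-mode allocation")
  allocate_expected(total_offspring, n_hosts, dist)
}

# Largest-remainder apportionment of clutch counts, then deterministic
# repair to hit the exact offspring total within the host limit.
allocate_expected <- function(total, n_hosts, dist) {
  mc <- dist$max_clutch
  m <- total / dist_mean(dist)            # expected number of clutches
  m_int <- max(1L, min(n_hosts, as.integer(round_half_away(m))))
  quota <- m_int * dist$p
  counts <- floor(quota)
  rem <- m_int - sum(counts)
  if (rem > 0) {
    frac <- quota - counts
    # ties broken toward smaller clutch sizes (stable order)
    idx <- order(-frac, seq_len(mc))[seq_len(rem)]
    counts[idx] <- counts[idx] + 1L
  }
  sizes <- rep.int(seq_len(mc), counts)
  if (length(sizes) == 0L) sizes <- 1L
  repeat {
    s <- sum(sizes)
    if (s == total && length(sizes) <= n_hosts) break
    if (s > total) {
      # shrink the largest clutch; drop it if it reaches zero
      i <- which.max(sizes)
      sizes[i] <- sizes[i] - 1L
      if (sizes[i] == 0L) sizes <- sizes[-i]
    } else if (s < total) {
      grow <- which(sizes < mc)
      if (length(grow) > 0L && length(sizes) >= n_hosts) {
        i <- grow[which.min(sizes[grow])]
        sizes[i] <- sizes[i] + 1L
      } else if (length(sizes) < n_hosts) {
        sizes <- c(sizes, 1L)
      } else {
        i <- grow[which.min(sizes[grow])]
        sizes[i] <- sizes[i] + 1L
      }
    } else {
      # correct total but too many hosts: merge the two smallest clutches
      o <- order(sizes)
      merged <- sizes[o[1L]] + sizes[o[2L]]
      if (merged > mc) {
        # split the merge across the cap: fill one to mc, keep remainder
        sizes[o[2L]] <- mc
        sizes[o[1L]] <- merged - mc
      } else {
        sizes[o[2L]] <- merged
        sizes <- sizes[-o[1L]]
      }
    }
  }
  sort(sizes, decreasing = TRUE)
}

#' Assign offspring sexes within clutches
#'
#' Given per-host clutch sizes, assigns female counts at a target female
#' proportion. The species' offspring sex ratio is close to 3:1
#' (male:female), i.e. \code{p_female = 0.25}, the default.
#'
#' Expected mode is deterministic: the total number of females is
#' \code{round(p_female * total offspring)} and females are placed one per
#' clutch in descending clutch-size order, wrapping around until exhausted
#' (so females are spread across hosts). Sampled mode draws each clutch's
#' female count binomially, seeded.
#'
#' @param clutch_sizes Integer vector of clutch sizes.
#' @param p_female Probability an offspring is female, in \code{[0, 1]}.
#' @param mode \code{"expected"} or \code{"sampled"}.
#' @param seed Optional integer seed for sampled mode.
#' @return data.frame with columns \code{size}, \code{females}, \code{males},
#'   one row per host in the input order.
#' @export
#' @examples
#' assign_sexes(4, p_female = 0.25)  # one female among four offspring
assign_sexes <- function(clutch_sizes, p_female = 0.25,
                         mode = c("expected", "sampled"), seed = NULL) {
  mode <- match.arg(mode)
  if (length(clutch_sizes) > 0 &&
      (any(clutch_sizes < 1) || any(clutch_sizes != trunc(clutch_sizes))))
    stop("clutch sizes must be whole numbers >= 1", call. = FALSE)
  if (!is.numeric(p_female) || p_female < 0 || p_female > 1)
    stop("`p_female` must be in [0, 1]", call. = FALSE)
  n <- length(clutch_sizes)
  if (n == 0L)
    return(data.frame(size = integer(0), females = integer(0),
                      males = integer(0)))
  sizes <- as.integer(clutch_sizes)
  if (mode == "sampled") {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    fem <- stats::rbinom(n, sizes, p_female)
  } else {
    total_f <- as.integer(round_half_away(p_female * sum(sizes)))
    fem <- integer(n)
    # visit hosts largest-clutch-first (ties by input order), one female per
    # visit, wrapping until the female total is placed
    ord <- order(-sizes, seq_len(n))
    while (total_f > 0L) {
      placed <- FALSE
      for (i in ord) {
        if (total_f == 0L) break
        if (fem[i] < sizes[i]) {
          fem[i] <- fem[i] + 1L
          total_f <- total_f - 1L
          placed <- TRUE
        }
      }
      if (!placed) break   # all clutches full (p_female = 1)
    }
  }
  data.frame(size = sizes, females = as.integer(fem),
             males = sizes - as.integer(fem))
}
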