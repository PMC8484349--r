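#' @title Tidy host-egg table schema
#' @description
#' All pipeline stages share one tidy table: one row per offered host egg,
#' columns \code{founder_id}, \code{group}, \code{substrate}
#' (\code{usual_plant} / \code{fictitious_plant} / \code{control_paper}),
#' \code{host_species} (\code{native} / \code{fictitious}),
#' \code{parasitized} (logical), \code{clutch_size} (NA when unparasitized),
#' \code{n_females} (NA when unparasitized) and \code{emerged} (logical:
#' whether parasitoid offspring emerged; always FALSE for fictitious hosts,
#' which cannot support larval development). Generator output adds
#' \code{host_beetle_emerged} for fictitious hosts.
#' @name host_egg_schema
NULL

HOST_EGG_COLS <- c("founder_id", "group", "substrate", "host_species",
                   "parasitized", "clutch_size", "n_females", "emerged")

validate_host_table <- function(tab) {
  miss <- setdiff(HOST_EGG_COLS, names(tab))
  if (length(miss) > 0)
    stop("host-egg table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- tab$parasitized & (is.na(tab$clutch_size) | tab$clutch_size < 1)
  if (any(bad))
    stop("parasitized rows must carry a clutch_size >= 1 (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")",
         call. = FALSE)
  bad <- !tab$parasitized & !is.na(tab$clutch_size)
  if (any(bad))
    stop("unparasitized rows must have NA clutch_size (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")",
         call. = FALSE)
  bad <- tab$parasitized & (tab$n_females < 0 | tab$n_females > tab$clutch_size)
  if (any(bad, na.rm = TRUE))
    stop("n_females must lie in 0..clutch_size", call. = FALSE)
  bad <- tab$host_species == "fictitious" & tab$emerged
  if (any(bad, na.rm = TRUE))
    stop("fictitious-host clutches cannot emerge (offspring cannot ",
         "complete development)", call. = FALSE)
  invisible(tab)
}

#' Read / write host-egg tables
#'
#' CSV dialect: comma-separated, UTF-8, mandatory header, logicals as
#' \code{true}/\code{false}. The reader validates the schema and the
#' per-row invariants (clutch present iff parasitized; fictitious clutches
#' never emerge).
#'
#' @param path CSV file path.
#' @param tab A host-egg table.
#' @return \code{read_host_table}: a validated data.frame.
#' @export
read_host_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("parasitized", "emerged", "host_beetle_emerged"),
                        names(tab)))
    tab[[col]] <- as.logical(tab[[col]])
  validate_host_table(tab)
}

#' @rdname read_host_table
#' @export
write_host_table <- function(tab, path) {
  validate_host_table(tab)
  out <- tab
  for (col in intersect(c("parasitized", "emerged", "host_beetle_emerged"),
                        names(out)))
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         ifelse(out[[col]], "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Project F2 fertility for each founder
#'
#' The two-generation projection: a founder's fitness is evaluated through
#' her grand-offspring. Each emerged daughter's future fertility is set by
#' the size of the clutch she developed in (larger natal clutch, smaller
#' body, lower fertility), so
#' \deqn{F2 = \sum_{\mathrm{hosts}\ h} \mathrm{females}_h \times
#'       \mathrm{fertility}(\mathrm{size}_h)}
#' over parasitized native hosts. Eggs laid into fictitious hosts count
#' against the founder's egg expenditure but contribute nothing to F1 or F2
#' fertility, because larvae cannot complete development there.
#'
#' @param tab Host-egg table (see [host_egg_schema]); may hold many founders.
#' @param model A [fertility_model()].
#' @return data.frame, one row per founder: \code{founder_id}, \code{group},
#'   \code{f1_eggs_laid} (all eggs laid, fictitious hosts included),
#'   \code{f1_fertility} (emerged offspring), \code{f1_females},
#'   \code{mean_clutch} (parasitized native hosts), \code{f2_fertility},
#'   \code{mean_offspring_fertility} (\code{f2/f1_females}; NA when no
#'   females emerged).
#' @export
#' @examples
#' tab <- data.frame(founder_id = "f1", group = "demo",
#'                   substrate = "usual_plant", host_species = "native",
#'                   parasitized = TRUE, clutch_size = c(1, 1, 1, 1),
#'                   n_females = c(1, 0, 0, 0), emerged = TRUE)
#' project_f2(tab)   # f2_fertility = 19
project_f2 <- function(tab, model = fertility_model()) {
  validate_host_table(tab)
  split_idx <- split(seq_len(nrow(tab)), tab$founder_id)
  rows <- lapply(names(split_idx), function(fid) {
    sub <- tab[split_idx[[fid]], ]
    par <- sub[sub$parasitized, , drop = FALSE]
    native <- par[par$host_species == "native", , drop = FALSE]
    f1_eggs <- sum(par$clutch_size)
    f1_fert <- sum(native$clutch_size)
    f1_fem <- sum(native$n_females)
    f2 <- if (nrow(native) > 0)
      sum(native$n_females * fertility_of_clutch(native$clutch_size, model))
    else 0
    data.frame(
      founder_id = fid,
      group = sub$group[1L],
      f1_eggs_laid = f1_eggs,
      f1_fertility = f1_fert,
      f1_females = f1_fem,
      mean_clutch = if (nrow(native) > 0) mean(native$clutch_size) else NA_real_,
      f2_fertility = f2,
      mean_offspring_fertility = if (f1_fem > 0) f2 / f1_fem else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare scenario groups on two-generation fitness
#'
#' Summarises per-group F1 and F2 fitness and reports pairwise percent
#' differences of per-offspring F2 fertility. The pooled per-offspring mean
#' is the ratio of sums (total F2 over total emerged females), which is
#' robust to founders with zero emerged females.
#'
#' @param tab Host-egg table with at least two groups, or a projection
#'   table from [project_f2()] (detected by its columns).
#' @param model A [fertility_model()].
#' @return List with \code{groups} (per-group summary data.frame) and
#'   \code{percent_diff} (data.frame of pairwise percent differences of the
#'   pooled per-offspring F2 mean, both directions:
#'   \code{(a - b) / b * 100}).
#' @export
compare_scenarios <- function(tab, model = fertility_model()) {
  proj <- if (all(c("f2_fertility", "f1_females") %in% names(tab))) tab
          else project_f2(tab, model)
  if (length(unique(proj$group)) < 2)
    stop("need at least two groups to compare", call. = FALSE)
  groups <- do.call(rbind, lapply(split(proj, proj$group), function(g) {
    fem <- sum(g$f1_females)
    data.frame(
      group = g$group[1L],
      n_founders = nrow(g),
      mean_f1_fertility = mean(g$f1_fertility),
      mean_clutch = mean(g$mean_clutch, na.rm = TRUE),
      mean_f2_fertility = mean(g$f2_fertility),
      total_f1_females = fem,
      per_offspring_f2 = if (fem > 0) sum(g$f2_fertility) / fem else NA_real_
    )
  }))
  rownames(groups) <- NULL
  usable <- groups[!is.na(groups$per_offspring_f2), , drop = FALSE]
  if (nrow(usable) < nrow(groups))
    warning("group(s) with zero emerged females excluded from percent ",
            "differences: ",
            paste(setdiff(groups$group, usable$group), collapse = ", "))
  pairs <- expand.grid(a = usable$group, b = usable$group,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  pd <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    va <- usable$per_offspring_f2[usable$group == pairs$a[i]]
    vb <- usable$per_offspring_f2[usable$group == pairs$b[i]]
    data.frame(group_a = pairs$a[i], group_b = pairs$b[i],
               percent_diff = (va - vb) / vb * 100)
  }))
  if (!is.null(pd)) rownames(pd) <- NULL
  list(groups = groups, percent_diff = pd)
}

#' Build a founder's host-egg table from a clutch-size frequency profile
#'
#' Convenience constructor behind scenario projections: places
#' \code{total_offspring} into at most \code{n_hosts} native host eggs
#' following a clutch-size frequency distribution (expected-mode
#' allocation), assigns sexes at \code{p_female}, and returns the tidy
#' host-egg rows for one representative founder.
#'
#' @param group Group label.
#' @param total_offspring Offspring the founder lays into native hosts.
#' @param n_hosts Native host eggs available.
#' @param dist A [clutch_dist()] of clutch-size frequencies.
#' @param p_female Female proportion (default 0.25, the 3:1 male:female
#'   ratio).
#' @param substrate Substrate label for the rows.
#' @param founder_id Identifier.
#' @return A host-egg table (parasitized rows only).
#' @export
founder_from_profile <- function(group, total_offspring, n_hosts, dist,
                                 p_female = 0.25, substrate = "usual_plant",
                                 founder_id = group) {
  sizes <- allocate_offspring(total_offspring, n_hosts, dist,
                              mode = "expected")
  sx <- assign_sexes(sizes, p_female, mode = "expected")
  if (nrow(sx) == 0L)
    return(data.frame(founder_id = character(0), group = character(0),
                      substrate = character(0), host_species = character(0),
                      parasitized = logical(0), clutch_size = integer(0),
                      n_females = integer(0), emerged = logical(0)))
  data.frame(founder_id = founder_id, group = group, substrate = substrate,
             host_species = "native", parasitized = TRUE,
             clutch_size = sx$size, n_females = sx$females, emerged = TRUE)
}
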