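## Inventory-level aggregation of profile results: coverage statistics,
## alerts-per-compound histograms, Sankey flow tables, and per-inventory
## Tier 1 domain proportions.

#' Coverage summary of a profiled inventory
#'
#' Counts classified/unclassified compounds, tabulates the
#' alerts-per-compound distribution (reported both in full and in the
#' 1 / 2 / >=3 binning used for inventory screening summaries), and counts
#' compounds per domain, group, subgroup and taxonomic-applicability label.
#' A compound counts once toward every category it touches, so category
#' counts can exceed the number of classified compounds.
#'
#' @param results a `profile_set` or list of `profile_result`.
#' @return list of class `coverage_summary`: `n_total`, `n_classified`,
#'   `n_unclassified`, `pct_unclassified`, `empty` (flag, `TRUE` for an
#'   empty input, where the percentage is reported as 0),
#'   `alerts_per_compound` (full table), `histogram` (named counts for
#'   `"1"`, `"2"`, `">=3"`), `by_domain`, `by_group`, `by_subgroup`,
#'   `taxa_counts`.
#' @export
coverage_summary <- function(results) {
  n_total <- length(results)
  st <- vapply(results, `[[`, character(1), "status")
  n_classified <- sum(st == "classified")
  n_match <- vapply(results, function(r) length(r$matches), integer(1))
  nm <- n_match[n_match > 0L]
  hist3 <- c("1" = sum(nm == 1L), "2" = sum(nm == 2L), ">=3" = sum(nm >= 3L))
  per_cat <- function(field) {
    v <- unlist(lapply(results, function(r)
      unique(vapply(r$matches, `[[`, character(1), field))))
    if (!length(v)) return(table(character(0)))
    sort(table(v), decreasing = TRUE)
  }
  taxa <- unlist(lapply(results, function(r)
    unique(unlist(lapply(r$matches, `[[`, "taxa")))))
  structure(list(
    n_total = n_total,
    n_classified = n_classified,
    n_unclassified = n_total - n_classified,
    pct_unclassified = if (n_total == 0) 0 else 100 * (n_total - n_classified) / n_total,
    empty = n_total == 0,
    alerts_per_compound = table(factor(nm)),
    histogram = hist3,
    by_domain = per_cat("domain_name"),
    by_group = per_cat("group_id"),
    by_subgroup = per_cat("subgroup_id"),
    taxa_counts = if (length(taxa)) sort(table(taxa), decreasing = TRUE) else table(character(0))
  ), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("Coverage: %d compounds, %d classified, %d unclassified (%.1f%%)\n",
              x$n_total, x$n_classified, x$n_unclassified, x$pct_unclassified))
  if (x$n_classified > 0) {
    cat("Alerts per compound: ",
        paste(sprintf("%s: %d", names(x$histogram), x$histogram), collapse = ", "), "\n")
    cat("By domain: ",
        paste(sprintf("%s: %d", names(x$by_domain), x$by_domain), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sankey flow table across the classification tiers
#'
#' Builds the `(source_node, target_node, count)` edge list for a Sankey
#' rendering of inventory -> domain -> group -> subgroup flows. Counts are
#' compound-category incidences: a compound matching alerts in two groups
#' contributes one unit to each group edge, so lower-tier totals may exceed
#' upper-tier ones. Unclassified compounds flow to a single
#' `"unclassified"` node.
#'
#' @param results a `profile_set` or list of `profile_result`.
#' @param inventory_name label of the root node.
#' @return data.frame of class `flow_table` with columns `source_node`,
#'   `target_node`, `count`, `level` (`"inventory>domain"`,
#'   `"domain>group"`, `"group>subgroup"`).
#' @export
sankey_flows <- function(results, inventory_name = "inventory") {
  edges <- list()
  bump <- function(level, s, t) {
    key <- paste(level, s, t, sep = "\r")
    edges[[key]] <<- if (is.null(edges[[key]])) 1L else edges[[key]] + 1L
  }
  for (r in results) {
    if (!length(r$matches)) {
      bump("inventory>domain", inventory_name, "unclassified")
      next
    }
    doms <- unique(vapply(r$matches, `[[`, character(1), "domain_name"))
    for (d in doms) bump("inventory>domain", inventory_name, d)
    grp <- unique(t(vapply(r$matches, function(m)
      c(m$domain_name, m$group_id), character(2))))
    for (i in seq_len(nrow(grp))) bump("domain>group", grp[i, 1], grp[i, 2])
    sg <- unique(t(vapply(r$matches, function(m)
      c(m$group_id, m$subgroup_id), character(2))))
    for (i in seq_len(nrow(sg))) bump("group>subgroup", sg[i, 1], sg[i, 2])
  }
  if (!length(edges)) {
    out <- data.frame(source_node = character(0), target_node = character(0),
                      count = integer(0), level = character(0),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(names(edges), "\r", fixed = TRUE)
    out <- data.frame(
      source_node = vapply(parts, `[[`, character(1), 2L),
      target_node = vapply(parts, `[[`, character(1), 3L),
      count = unlist(edges, use.names = FALSE),
      level = vapply(parts, `[[`, character(1), 1L),
      stringsAsFactors = FALSE
    )
    out <- out[order(match(out$level, c("inventory>domain", "domain>group",
                                        "group>subgroup")), out$target_node), ]
    rownames(out) <- NULL
  }
  class(out) <- c("flow_table", "data.frame")
  out
}

#' Tier 1 domain proportions per inventory
#'
#' For each named inventory, the proportion of compound-domain incidences
#' (default, `mode = "exclusive"`) or of compounds (`mode =
#' "multi_label"`) falling in each Tier 1 domain or remaining
#' unclassified. In exclusive mode a compound touching several domains
#' contributes one unit to each, and the denominator is the number of
#' incidences, so each inventory's proportions sum to 1; in multi-label
#' mode the denominator is the number of compounds, so proportions can sum
#' to more than 1.
#'
#' @param named_results named list: inventory name -> `profile_set`.
#' @param mode `"exclusive"` or `"multi_label"`.
#' @return data.frame of class `domain_proportions` with columns
#'   `inventory_name`, `category` (domain name or `"unclassified"`),
#'   `n`, `proportion`.
#' @export
domain_proportions <- function(named_results, mode = c("exclusive", "multi_label")) {
  mode <- match.arg(mode)
  stopifnot(is.list(named_results), length(names(named_results)) == length(named_results))
  cats <- c(unname(DOMAIN_NAMES), "unclassified")
  rows <- lapply(names(named_results), function(nm) {
    res <- named_results[[nm]]
    if (!length(res)) stop("inventory '", nm, "' is empty")
    counts <- stats::setNames(rep(0L, length(cats)), cats)
    n_incidence <- 0L
    for (r in res) {
      doms <- if (length(r$matches))
        unique(vapply(r$matches, `[[`, character(1), "domain_name")) else "unclassified"
      counts[doms] <- counts[doms] + 1L
      n_incidence <- n_incidence + length(doms)
    }
    denom <- if (mode == "exclusive") n_incidence else length(res)
    data.frame(inventory_name = nm, category = cats, n = as.integer(counts),
               proportion = as.numeric(counts) / denom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("domain_proportions", "data.frame")
  out
}

#' Barplot of Tier 1 domain proportions
#'
#' Stacked horizontal barplot, one bar per inventory, segments per domain
#' plus unclassified.
#'
#' @param x a `domain_proportions` table.
#' @param ... passed to [graphics::barplot()].
#' @return the barplot midpoints, invisibly.
#' @export
plot.domain_proportions <- function(x, ...) {
  m <- t(do.call(rbind, lapply(split(x, x$inventory_name), function(d)
    stats::setNames(d$proportion, d$category))))
  graphics::barplot(m, horiz = TRUE, las = 1,
                    col = c("#4878a8", "#d65f5f", "#6aa84f", "grey80"),
                    xlab = "proportion of inventory",
                    legend.text = rownames(m), ...)
}
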