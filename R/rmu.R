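#' Load a table of published sex-biased mutation-rate estimates
#'
#' Reads a delimited file of \eqn{R_\mu} (male/female per-site mutation
#' rate) estimates with columns `species`, `lineage_group`, `estimate`,
#' `ci_low`, `ci_high`, `method`, `source`, `species_level`. Files in
#' other dialects are bridged by `col_map`, a named character vector
#' mapping the canonical names to the file's column names. Rows
#' violating the record invariants (non-positive or unparseable
#' estimates, bounds not bracketing the estimate) are dropped and
#' reported, with their line numbers, in the `"rejected"` attribute;
#' rows in = valid records + rejected rows.
#'
#' @param path CSV or TSV file (delimiter inferred from extension).
#' @param col_map Optional named character vector, e.g.
#'   `c(estimate = "Rmu_point")`.
#' @return A data frame of validated records with attribute
#'   `"rejected"` (data frame of `line`, `reason`).
#' @export
load_rmu <- function(path, col_map = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  required <- c("species", "lineage_group", "estimate")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  optional <- c("ci_low", "ci_high", "method", "source", "species_level")
  for (col in optional) if (!(col %in% names(raw))) raw[[col]] <- NA
  est <- suppressWarnings(as.numeric(raw$estimate))
  lo <- suppressWarnings(as.numeric(raw$ci_low))
  hi <- suppressWarnings(as.numeric(raw$ci_high))
  lvl <- raw$species_level
  lvl <- ifelse(is.na(lvl) | lvl == "", TRUE,
                tolower(lvl) %in% c("true", "t", "1", "yes"))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(est)] <- "estimate not a number"
  reason[is.na(reason) & est <= 0] <- "estimate must be positive"
  bad_ci <- is.na(reason) & !is.na(lo) & !is.na(hi) &
    !(lo <= est & est <= hi)
  reason[bad_ci] <- "bounds do not bracket the estimate"
  keep <- is.na(reason)
  rejected <- data.frame(line = which(!keep) + 1L,  # +1 for the header
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0) {
    warning(sprintf("%d row(s) rejected, e.g. line %d: %s",
                    nrow(rejected), rejected$line[1], rejected$reason[1]),
            call. = FALSE)
  }
  out <- data.frame(
    species = raw$species[keep], lineage_group = raw$lineage_group[keep],
    estimate = est[keep], ci_low = lo[keep], ci_high = hi[keep],
    method = as.character(raw$method)[keep],
    source = as.character(raw$source)[keep],
    species_level = lvl[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- rejected
  out
}

#' Exclude estimates by name or threshold
#'
#' Curation step applied before per-species averaging, mirroring the
#' usual handling of implausible literature values (e.g. a single
#' \eqn{R_\mu \sim 20} estimate for humans): records can be excluded by
#' `(species, source)` name or by an upper threshold on the estimate.
#' Exclusion happens before [species_average()] so an outlier cannot
#' contaminate its species' mean. An audit log of what was removed and
#' why is attached as attribute `"audit"`; naming an absent record
#' warns rather than errs.
#'
#' @param records Record table from [load_rmu()] or
#'   [sample_rmu_table()].
#' @param exclude_species Character vector of species names whose
#'   records are dropped entirely, or a data frame with columns
#'   `species` and `source` to drop single estimates.
#' @param threshold Upper limit; estimates above it are dropped.
#' @return Filtered records with attribute `"audit"`.
#' @export
apply_exclusions <- function(records, exclude_species = NULL,
                             threshold = NULL) {
  drop <- rep(FALSE, nrow(records))
  why <- rep(NA_character_, nrow(records))
  if (!is.null(threshold)) {
    over <- records$estimate > threshold
    why[over & !drop] <- sprintf("estimate > threshold %g", threshold)
    drop <- drop | over
  }
  if (!is.null(exclude_species)) {
    if (is.data.frame(exclude_species)) {
      key <- paste(records$species, records$source, sep = "\r")
      target <- paste(exclude_species$species, exclude_species$source,
                      sep = "\r")
      hit <- key %in% target
      absent <- !(target %in% key)
      if (any(absent)) {
        warning("exclusion names absent record(s): ",
                paste(exclude_species$species[absent], collapse = ", "),
                call. = FALSE)
      }
    } else {
      hit <- records$species %in% exclude_species
      absent <- !(exclude_species %in% records$species)
      if (any(absent)) {
        warning("exclusion names absent species: ",
                paste(exclude_species[absent], collapse = ", "),
                call. = FALSE)
      }
    }
    why[hit & !drop] <- "named exclusion"
    drop <- drop | hit
  }
  audit <- data.frame(species = records$species[drop],
                      source = records$source[drop],
                      estimate = records$estimate[drop],
                      reason = why[drop], stringsAsFactors = FALSE)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Average multiple estimates per species
#'
#' Species with several published estimates are collapsed to one row
#' carrying the arithmetic mean; only species-level records enter
#' (multi-species lineage aggregates are set aside). Idempotent: a
#' table already holding one estimate per species passes through
#' unchanged.
#'
#' @param records Record table.
#' @return One row per species: `species`, `lineage_group`, `estimate`
#'   (mean), `n_estimates`.
#' @export
species_average <- function(records) {
  records <- records[records$species_level %in% TRUE, , drop = FALSE]
  if (nrow(records) == 0) {
    return(data.frame(species = character(), lineage_group = character(),
                      estimate = numeric(), n_estimates = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(estimate ~ species + lineage_group,
                          data = records, FUN = mean)
  cnt <- stats::aggregate(cbind(n_estimates = estimate) ~ species +
                            lineage_group, data = records, FUN = length)
  out <- merge(agg, cnt, by = c("species", "lineage_group"))
  out$species_level <- TRUE
  out <- out[order(out$lineage_group, out$species), ]
  rownames(out) <- NULL
  out
}

#' Summarize per-species estimates by lineage group
#'
#' @param per_species Per-species table from [species_average()].
#' @param probs Quantile probabilities defining the reported central
#'   range (default central 90%).
#' @return One row per group: `lineage_group`, `n`, `mean`, `median`,
#'   `lower`, `upper`.
#' @export
group_summary <- function(per_species, probs = c(0.05, 0.95)) {
  if (nrow(per_species) == 0) stop("empty per-species table", call. = FALSE)
  groups <- split(per_species$estimate, per_species$lineage_group)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- stats::quantile(v, probs = probs, names = FALSE)
    data.frame(lineage_group = g, n = length(v), mean = mean(v),
               median = stats::median(v), lower = q[1], upper = q[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full estimate-curation pipeline
#'
#' Fixed order: named/threshold exclusions, then per-species averaging,
#' then group summaries. Exclusions come first so an excluded outlier
#' never enters its species' average.
#'
#' @param records Record table from [load_rmu()].
#' @inheritParams apply_exclusions
#' @return List with `records` (post-exclusion), `per_species`,
#'   `summary`, `audit`, and `n_species` (the number of species-level
#'   estimates after curation).
#' @export
rmu_pipeline <- function(records, exclude_species = NULL,
                         threshold = NULL) {
  kept <- apply_exclusions(records, exclude_species = exclude_species,
                           threshold = threshold)
  per_species <- species_average(kept)
  list(records = kept, per_species = per_species,
       summary = group_summary(per_species),
       audit = attr(kept, "audit"),
       n_species = nrow(per_species))
}
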