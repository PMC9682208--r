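# Tidy data model for competitive mating-assay results.
#
# One row per focal individual. Each focal male was assayed in a group with
# one marked competitor male and two partner females; offspring are assigned
# to the focal or the competitor by a dominant visible marker. Focal females
# have a single clutch: stored in the p1_* pair with sired == total, p2_*
# empty.

#' @name fitness_schema
#' @title CSV schema for fitness tables
#' @description Column order and enum levels for the tidy fitness table.
#' @keywords internal
NULL

fitness_columns <- c(
  "focal_id", "sex", "flour", "yeast", "assay", "genotype", "body_mass_mg",
  "survived", "p1_total", "p1_sired", "p2_total", "p2_sired", "laying_week"
)

fitness_levels <- list(
  sex = c("male", "female"),
  flour = c("wheat", "whole_wheat"),
  yeast = c("control_5pct", "low_1pct", "none"),
  assay = c("focal_only", "whole_group"),
  genotype = c("wildtype", "Rd"),
  laying_week = c("week1", "week2", "combined")
)

count_cols <- c("p1_total", "p1_sired", "p2_total", "p2_sired")

violation <- function(row, focal_id, rule, message) {
  data.frame(row = row, focal_id = as.character(focal_id), rule = rule,
             message = message, stringsAsFactors = FALSE)
}

empty_violations <- function() {
  data.frame(row = integer(0), focal_id = character(0), rule = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

validate_fitness <- function(df) {
  v <- list(empty_violations())
  bad <- function(rows, rule, msg) {
    rows <- which(rows)
    if (length(rows)) {
      v[[length(v) + 1]] <<- violation(rows, df$focal_id[rows], rule,
                                       sprintf(msg, df$focal_id[rows]))
    }
  }

  for (col in names(fitness_levels)) {
    if (col == "laying_week") next
    bad(!(df[[col]] %in% fitness_levels[[col]]), paste0("enum_", col),
        paste0("unknown ", col, " level for focal '%s'"))
  }
  lw <- df$laying_week
  bad(!(is.na(lw) | lw == "" | lw %in% fitness_levels$laying_week),
      "enum_laying_week", "unknown laying_week level for focal '%s'")

  for (col in count_cols) {
    x <- df[[col]]
    bad(!is.na(x) & (x < 0 | x != round(x)), paste0("count_", col),
        paste0(col, " must be a nonnegative integer (focal '%s')"))
  }
  bad(!is.na(df$body_mass_mg) & df$body_mass_mg < 0, "body_mass_nonneg",
      "body_mass_mg must be nonnegative (focal '%s')")

  # sired <= total, per partner
  bad(!is.na(df$p1_sired) & !is.na(df$p1_total) & df$p1_sired > df$p1_total,
      "sired_le_total",
      "p1_sired exceeds p1_total for focal '%s'")
  bad(!is.na(df$p2_sired) & !is.na(df$p2_total) & df$p2_sired > df$p2_total,
      "sired_le_total",
      "p2_sired exceeds p2_total for focal '%s'")

  # female single-clutch convention
  fem <- df$sex == "female"
  bad(fem & (!is.na(df$p2_total) | !is.na(df$p2_sired)), "female_p2_empty",
      "female focal '%s' must have empty p2_* columns")
  bad(fem & !is.na(df$p1_total) & !is.na(df$p1_sired) &
        df$p1_sired != df$p1_total, "female_sired_eq_total",
      "female focal '%s' must have p1_sired == p1_total")

  # low yeast (1%) exists only in the whole-wheat arm of the design
  bad(df$yeast == "low_1pct" & df$flour != "whole_wheat", "low_yeast_flour",
      "yeast 'low_1pct' only occurs with whole_wheat flour (focal '%s')")

  # focal_id unique within design cell
  cell <- interaction(df$assay, df$sex, df$flour, df$yeast, drop = TRUE)
  key <- paste(cell, df$focal_id)
  bad(duplicated(key) | duplicated(key, fromLast = TRUE), "unique_focal_id",
      "duplicated focal_id '%s' within its (assay, sex, flour, yeast) cell")

  do.call(rbind, v)
}

#' Construct a validated fitness dataset from a data frame
#'
#' @param df Data frame with the columns of the CSV schema (see
#'   [read_fitness_table()]); `laying_week` may be omitted.
#' @param provenance Free-text provenance string carried on the object.
#' @param strict If `TRUE`, any invariant violation aborts; if `FALSE`,
#'   violations are kept in the validation report and offending rows are
#'   marked in a logical `flagged` column (never silently dropped).
#' @return A `fitness_data` object: a data.frame with attributes
#'   `provenance` and `validation` (a data.frame of violations).
#' @export
as_fitness_data <- function(df, provenance = "in-memory", strict = TRUE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(fitness_columns, "laying_week"), names(df))
  if (length(missing_cols)) {
    stop("fitness table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"laying_week" %in% names(df)) df$laying_week <- NA_character_
  df$focal_id <- as.character(df$focal_id)
  for (col in count_cols) df[[col]] <- as.numeric(df[[col]])
  df$body_mass_mg <- as.numeric(df$body_mass_mg)
  df$survived <- as.logical(df$survived)
  df$laying_week[!is.na(df$laying_week) & df$laying_week == ""] <-
    NA_character_
  df <- df[, fitness_columns]

  report <- validate_fitness(df)
  if (strict && nrow(report) > 0) {
    stop("fitness table validation failed:\n  ",
         paste(utils::head(report$message, 10), collapse = "\n  "),
         if (nrow(report) > 10) sprintf("\n  ... and %d more",
                                        nrow(report) - 10) else "")
  }
  df$flagged <- seq_len(nrow(df)) %in% report$row
  structure(df,
            provenance = provenance,
            validation = report,
            class = c("fitness_data", "data.frame"))
}

#' Read a tidy fitness table from CSV
#'
#' Expected schema (UTF-8, comma-separated, header required):
#' `focal_id, sex, flour, yeast, assay, genotype, body_mass_mg, survived,
#' p1_total, p1_sired, p2_total, p2_sired, laying_week`.
#' Females carry their clutch in `p1_total` with `p1_sired == p1_total` and
#' empty `p2_*`. A totals-only dialect, in which males pool both partners
#' into `p1_*` and every male `p2_*` entry is empty, is accepted; such data
#' support all analyses except the male variance decomposition (see
#' [per_partner_available()]).
#'
#' @param path Path to the CSV file.
#' @param strict Abort on any invariant violation (default); otherwise flag.
#' @return A `fitness_data` object.
#' @seealso [write_fitness_table()], [as_fitness_data()]
#' @export
read_fitness_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(focal_id = "character"))
  if (nrow(df) == 0) stop("fitness table schema error: no data rows in ", path)
  as_fitness_data(df, provenance = normalizePath(path), strict = strict)
}

#' Write a fitness dataset to CSV
#'
#' Round-trips losslessly through [read_fitness_table()].
#'
#' @param x A `fitness_data` object (or conforming data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fitness_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, fitness_columns], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validation report of a dataset
#' @param x A `fitness_data` object.
#' @return Data frame with columns `row`, `focal_id`, `rule`, `message`.
#' @export
validation_report <- function(x) attr(x, "validation")

#' Are per-partner offspring counts available?
#'
#' `FALSE` for the totals-only dialect (all male `p2_*` empty while male
#' rows exist), in which case the male variance decomposition is disabled.
#' @param x A `fitness_data` object or conforming data.frame.
#' @export
per_partner_available <- function(x) {
  m <- x$sex == "male"
  if (!any(m)) return(FALSE)
  any(!is.na(x$p2_total[m]) | !is.na(x$p2_sired[m]))
}

#' @export
print.fitness_data <- function(x, ...) {
  rep <- validation_report(x)
  cat(sprintf("<fitness_data> %d focal individuals (%d male, %d female), %s\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              if (per_partner_available(x)) "per-partner counts"
              else "totals only"))
  cat(sprintf("  provenance: %s\n  violations: %d\n",
              attr(x, "provenance"), if (is.null(rep)) 0L else nrow(rep)))
  NextMethod()
}

#' Reproductive success of each focal individual
#'
#' W = total number of offspring sired by (males) or produced by (females)
#' the focal: the sum over partners of focal-sired offspring. For females
#' this is her clutch total. Invariant to partner ordering.
#'
#' @param x A `fitness_data` object or conforming data.frame.
#' @return Nonnegative numeric vector, one entry per row of `x`.
#' @export
reproductive_success <- function(x) {
  s1 <- ifelse(is.na(x$p1_sired), 0, x$p1_sired)
  s2 <- ifelse(is.na(x$p2_sired), 0, x$p2_sired)
  as.numeric(s1 + s2)
}

#' Per-female-scaled male reproductive success
#'
#' Divides a male's total sired offspring by the number of partner females
#' in his group, for display alongside female values. Both the selection
#' coefficient and the opportunity for selection are invariant to this
#' common rescaling, so it is never used inside those estimators.
#'
#' @param x A `fitness_data` object (male rows).
#' @param n_partners Number of partner females per group (design constant, 2).
#' @return Numeric vector.
#' @export
per_female_scaled_success <- function(x, n_partners = 2) {
  if (any(n_partners < 1)) stop("n_partners must be >= 1")
  if (any(x$sex != "male")) stop("per-female scaling applies to male records")
  reproductive_success(x) / n_partners
}

#' Subset a dataset to one design cell
#'
#' @param x A `fitness_data` object.
#' @param sex,flour,yeast,assay Optional enum values; `NULL` means no filter.
#' @param include_dead Keep individuals that died during the laying period
#'   (default `TRUE`: mortality is part of realised fitness).
#' @return `fitness_data` subset (attributes preserved).
#' @export
cell_subset <- function(x, sex = NULL, flour = NULL, yeast = NULL,
                        assay = NULL, include_dead = TRUE) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(sex)) keep <- keep & x$sex %in% sex
  if (!is.null(flour)) keep <- keep & x$flour %in% flour
  if (!is.null(yeast)) keep <- keep & x$yeast %in% yeast
  if (!is.null(assay)) keep <- keep & x$assay %in% assay
  if (!include_dead) keep <- keep & x$survived
  out <- x[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(x, "provenance")
  attr(out, "validation") <- attr(x, "validation")
  class(out) <- class(x)
  out
}
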