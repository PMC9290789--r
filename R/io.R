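# TSV readers/writers for the four assay-table schemas. Tables are
# tab-separated with a header row; lines starting with '#' are comments
# (the writers use them to stamp the configuration hash).

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop_missing_input(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sub("\r$", "", lines) # tolerate CRLF line endings
}

# Returns a data.frame of character columns plus the source line number of
# each row, so parse errors can point at the offending line.
read_raw_table <- function(path) {
  lines <- read_tsv_lines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  if (length(lineno) < 1L) stop_empty_input(sprintf("no content in %s", path))
  df <- read.delim(text = paste(lines[keep], collapse = "\n"),
                   sep = "\t", header = TRUE, colClasses = "character",
                   quote = "", stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "source_lines") <- lineno[-1L]
  attr(df, "source_path") <- path
  df
}

require_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_schema(sprintf("%s: missing required column(s): %s",
                        attr(df, "source_path") %||% "table",
                        paste(missing, collapse = ", ")))
  }
}

as_numeric_column <- function(df, col) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & nzchar(trimws(raw)))
  if (length(bad) > 0L) {
    lines <- attr(df, "source_lines")
    stop_parse(sprintf("%s: non-numeric value '%s' in column '%s' at line %d",
                       attr(df, "source_path") %||% "table",
                       raw[bad[1]], col,
                       if (is.null(lines)) bad[1] else lines[bad[1]]))
  }
  val
}

#' Read an eclosion table
#'
#' Tab-separated with header; required columns `fly_id`, `population`,
#' `days_to_eclosion` (non-negative). Lines beginning `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_eclosion <- function(path) {
  df <- read_raw_table(path)
  require_columns(df, c("fly_id", "population", "days_to_eclosion"))
  out <- data.frame(fly_id = df$fly_id, population = df$population,
                    days_to_eclosion = as_numeric_column(df, "days_to_eclosion"),
                    stringsAsFactors = FALSE)
  if (any(out$days_to_eclosion < 0)) {
    stop_validation(sprintf("%s: days_to_eclosion must be non-negative", path))
  }
  out
}

#' Read a mating-trial table
#'
#' Required columns: `pair_female`, `pair_male`, `n_matings`,
#' `hours_observed`, `cross_class` (one of `parental`, `hybrid`).
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_matings <- function(path) {
  df <- read_raw_table(path)
  require_columns(df, c("pair_female", "pair_male", "n_matings",
                        "hours_observed", "cross_class"))
  out <- data.frame(
    pair_female = df$pair_female, pair_male = df$pair_male,
    n_matings = as_numeric_column(df, "n_matings"),
    hours_observed = as_numeric_column(df, "hours_observed"),
    cross_class = df$cross_class, stringsAsFactors = FALSE
  )
  if (!all(out$cross_class %in% c("parental", "hybrid"))) {
    stop_validation(sprintf("%s: cross_class must be 'parental' or 'hybrid'", path))
  }
  if (any(out$n_matings < 0) || any(out$hours_observed <= 0)) {
    stop_validation(sprintf("%s: counts must be >= 0 and hours positive", path))
  }
  out
}

validate_crosses <- function(crosses, path = "cross table") {
  need <- c("cage_id", "maternal_pop", "paternal_pop", "cage_females",
            "cage_males", "days_observed", "eggs_laid", "eggs_hatched")
  if (!is.data.frame(crosses)) stop_invalid_parameter("`crosses` must be a data.frame")
  missing <- setdiff(need, names(crosses))
  if (length(missing) > 0L) {
    stop_schema(sprintf("%s: missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  num <- c("cage_females", "cage_males", "days_observed", "eggs_laid", "eggs_hatched")
  for (col in num) {
    if (!is.numeric(crosses[[col]]) || any(is.na(crosses[[col]]))) {
      stop_validation(sprintf("%s: column '%s' must be numeric and complete", path, col))
    }
  }
  if (any(crosses$eggs_laid < 0) || any(crosses$eggs_hatched < 0)) {
    stop_validation(sprintf("%s: egg counts must be non-negative", path))
  }
  if (any(crosses$eggs_hatched > crosses$eggs_laid)) {
    stop_validation(sprintf("%s: eggs_hatched exceeds eggs_laid", path))
  }
  if (any(crosses$days_observed <= 0)) {
    stop_validation(sprintf("%s: days_observed must be positive", path))
  }
  invisible(crosses)
}

#' Read a cross (egg-hatch) table
#'
#' Required columns: `cage_id`, `maternal_pop`, `paternal_pop`,
#' `cage_females`, `cage_males`, `days_observed`, `eggs_laid`,
#' `eggs_hatched`, with `eggs_hatched <= eggs_laid`.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_crosses <- function(path) {
  df <- read_raw_table(path)
  require_columns(df, c("cage_id", "maternal_pop", "paternal_pop",
                        "cage_females", "cage_males", "days_observed",
                        "eggs_laid", "eggs_hatched"))
  out <- data.frame(
    cage_id = df$cage_id, maternal_pop = df$maternal_pop,
    paternal_pop = df$paternal_pop,
    cage_females = as_numeric_column(df, "cage_females"),
    cage_males = as_numeric_column(df, "cage_males"),
    days_observed = as_numeric_column(df, "days_observed"),
    eggs_laid = as_numeric_column(df, "eggs_laid"),
    eggs_hatched = as_numeric_column(df, "eggs_hatched"),
    stringsAsFactors = FALSE
  )
  validate_crosses(out, path)
  out
}

#' Read an endosymbiont infection survey
#'
#' Required columns: `fly_id`, `population`, `wCin2`, `wCin3` (presence coded
#' 1/0).
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_survey <- function(path) {
  df <- read_raw_table(path)
  require_columns(df, c("fly_id", "population", "wCin2", "wCin3"))
  out <- data.frame(
    fly_id = df$fly_id, population = df$population,
    wCin2 = as_numeric_column(df, "wCin2"),
    wCin3 = as_numeric_column(df, "wCin3"),
    stringsAsFactors = FALSE
  )
  if (!all(out$wCin2 %in% c(0, 1)) || !all(out$wCin3 %in% c(0, 1))) {
    stop_validation(sprintf("%s: wCin2/wCin3 must be coded 0 or 1", path))
  }
  out
}

#' Write a table as tab-separated text
#'
#' Writes a data.frame as a TSV with a header row, preceded by optional `#`
#' comment lines (used by the pipeline to stamp each output with the
#' configuration hash). Missing values are written as empty strings.
#'
#' @param x Data.frame to write.
#' @param path Output path.
#' @param comments Character vector of comment lines (written as `# <line>`).
#' @return `path`, invisibly.
#' @export
write_assay_tsv <- function(x, path, comments = character()) {
  con <- file(path, open = "wb") # binary mode: byte-identical output across platforms
  on.exit(close(con))
  if (length(comments) > 0L) {
    writeLines(paste0("# ", comments), con, sep = "\n")
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "", eol = "\n")
  invisible(path)
}

#' Pool a mating table into a per-pair tally
#'
#' Pools reciprocal hybrid directions into `H` and both parental types into
#' `C` for one population pair, computing per-hour rates within each class so
#' that assays observed for different lengths of time can be compared on a
#' standardized scale.
#'
#' @param matings Mating table (see [read_matings()]).
#' @param pair Optional character vector of the two populations to keep; by
#'   default all rows are pooled.
#' @return A [mating_tally()].
#' @export
matings_to_tally <- function(matings, pair = NULL) {
  if (is.null(pair)) {
    pops <- unique(c(matings$pair_female, matings$pair_male))
    if (length(pops) != 2L) {
      stop_invalid_parameter("`matings` spans more than one pair; supply `pair`")
    }
    pair <- pops
  }
  sub <- matings[matings$pair_female %in% pair & matings$pair_male %in% pair, ,
                 drop = FALSE]
  if (nrow(sub) == 0L) {
    stop_missing_input(sprintf("no mating rows for pair %s-%s", pair[1], pair[2]))
  }
  hyb <- sub$cross_class == "hybrid"
  H <- sum(sub$n_matings[hyb])
  C <- sum(sub$n_matings[!hyb])
  tal <- mating_tally(pair, H = H, C = C,
                      hours_observed = sum(sub$hours_observed), table = sub)
  # class-specific per-hour rates (the totals above share one clock)
  if (any(hyb)) tal$rate_H <- H / sum(sub$hours_observed[hyb])
  if (any(!hyb)) tal$rate_C <- C / sum(sub$hours_observed[!hyb])
  tal
}
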