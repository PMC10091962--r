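#' @include utils.R AllClasses.R
NULL

.brainRegions <- c("telencephalon", "optic_tectum", "cerebellum",
                   "dorsal_medulla", "hypothalamus", "olfactory_bulbs")

.regionDimColumns <- function() {
  as.vector(t(outer(.brainRegions, c("length", "width", "height"),
                    function(r, d) paste0(r, "_", d, "_mm"))))
}

.traitTableColumns <- function() {
  c("individual_id", "group", "generation", "sex", "body_length_mm",
    "brain_weight_mg", .regionDimColumns())
}

.trialLogColumns <- function() {
  c("individual_id", "group", "sex", "task", "trial_index", "correct")
}

#' Brain region names used in the trait table
#' @return Character vector of the six measured brain regions.
#' @export
brainRegions <- function() .brainRegions

# read.csv with the named columns pinned to character (an all-female sex
# column would otherwise be sniffed as logical "F" -> FALSE).
.readCsvTyped <- function(path, charCols) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = TRUE))
  cc <- stats::setNames(rep("character", length(intersect(charCols, header))),
                        intersect(charCols, header))
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"), colClasses = cc)
}

#' Read an individual-level trait table
#'
#' Parses the CSV schema `individual_id, group, generation, sex,
#' body_length_mm, brain_weight_mg, <region>_{length,width,height}_mm` for
#' the six brain regions. Mandatory columns are individual_id, group,
#' generation, sex and body_length_mm; brain weight and region dimensions are
#' optional per individual (empty cells become NA, never zero). Every
#' violation is reported with the offending data row and column.
#'
#' @param path CSV file (comma-separated, UTF-8, header row, "." decimal).
#' @return data.frame of validated individual records.
#' @export
readTraitTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .readCsvTyped(path,
                      c("individual_id", "group", "generation", "sex"))
  mandatory <- c("individual_id", "group", "generation", "sex",
                 "body_length_mm")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (cl in setdiff(.traitTableColumns(), names(df))) df[[cl]] <- NA_real_
  df <- df[, .traitTableColumns()]
  validateTraitRecords(df)
  df
}

#' Validate a collection of individual records
#'
#' Checks the invariants of the trait-table schema: unique ids, known group
#' labels, group/generation consistency, and strictly positive finite
#' measurements wherever present.
#'
#' @param records data.frame in the trait-table schema.
#' @return The records, invisibly, if valid; otherwise an error naming the
#'   first offending row and column.
#' @export
validateTraitRecords <- function(records) {
  if (anyDuplicated(records$individual_id)) {
    dup <- records$individual_id[duplicated(records$individual_id)][1]
    stop("validation error: duplicate individual_id '", dup, "'")
  }
  badGroup <- which(!records$group %in% crossingGroups())
  if (length(badGroup))
    stop("validation error: row ", badGroup[1], ", column group: unknown ",
         "label '", records$group[badGroup[1]], "'")
  expected <- .generationOf(records$group)
  badGen <- which(records$generation != expected)
  if (length(badGen))
    stop("validation error: row ", badGen[1], ", column generation: '",
         records$generation[badGen[1]], "' inconsistent with group '",
         records$group[badGen[1]], "'")
  badSex <- which(!records$sex %in% c("F", "M"))
  if (length(badSex))
    stop("validation error: row ", badSex[1], ", column sex")
  numCols <- c("body_length_mm", "brain_weight_mg", .regionDimColumns())
  for (cl in numCols) {
    v <- records[[cl]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (any(is.na(v) & !is.na(records[[cl]])))
        stop("validation error: column ", cl, ": non-numeric value")
      records[[cl]] <- v
    }
    mandatory <- cl == "body_length_mm"
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (mandatory) bad <- union(bad, which(is.na(v)))
    if (length(bad)) {
      bad <- sort(bad)
      stop("validation error: row ", bad[1], ", column ", cl,
           ": measurements must be strictly positive and finite")
    }
  }
  invisible(records)
}

#' Write an individual-level trait table
#'
#' Inverse of [readTraitTable()]: comma-separated, header row, empty string
#' for missing values. Read-then-write is the identity on valid tables (to
#' floating-point printing precision).
#'
#' @param records data.frame in the trait-table schema.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeTraitTable <- function(records, path) {
  validateTraitRecords(records)
  out <- records
  for (cl in names(out))
    if (is.numeric(out[[cl]])) out[[cl]] <- format(out[[cl]], digits = 15,
                                                   trim = TRUE)
  out[is.na(records)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trial-level learning log
#'
#' Parses the CSV schema `individual_id, group, sex, task, trial_index,
#' correct` and returns it sorted by individual, task and trial index.
#' Duplicate (individual, task, trial) entries, non-contiguous trial indices
#' (they must run 1, 2, ... without gaps) and non-binary outcomes are
#' errors.
#'
#' @param path CSV file.
#' @return Validated, sorted data.frame of trial records.
#' @export
readTrialLog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .readCsvTyped(path, c("individual_id", "group", "sex", "task"))
  miss <- setdiff(c("individual_id", "task", "trial_index", "correct"),
                  names(df))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (cl in setdiff(.trialLogColumns(), names(df))) df[[cl]] <- NA_character_
  df <- df[, .trialLogColumns()]
  validateTrialLog(df)
}

#' Validate a trial log
#'
#' @param df data.frame in the trial-log schema.
#' @return The log sorted by (individual_id, task, trial_index).
#' @export
validateTrialLog <- function(df) {
  if (!all(df$task %in% c("associative", "reversal")))
    stop("validation error: task must be 'associative' or 'reversal'")
  if (!is.numeric(df$trial_index) || any(df$trial_index < 1) ||
      any(df$trial_index != as.integer(df$trial_index)))
    stop("validation error: trial_index must be integers >= 1")
  if (!all(df$correct %in% c(0, 1)))
    stop("validation error: correct must be binary (0/1)")
  key <- paste(df$individual_id, df$task, df$trial_index, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate-record error: individual '", df$individual_id[i],
         "', task '", df$task[i], "', trial ", df$trial_index[i])
  }
  df <- df[order(df$individual_id, df$task, df$trial_index), ]
  for (k in unique(paste(df$individual_id, df$task, sep = "\r"))) {
    idx <- df$trial_index[paste(df$individual_id, df$task, sep = "\r") == k]
    if (!identical(as.integer(idx), seq_along(idx))) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      stop("contiguity error: individual '", parts[1], "', task '",
           parts[2], "': trial indices must run 1..", length(idx),
           " without gaps")
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a trial-level learning log
#'
#' @param trials data.frame in the trial-log schema.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeTrialLog <- function(trials, path) {
  validateTrialLog(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate per-group success counts across experiment stages
#'
#' Builds the count table underlying printed success summaries: per
#' (group, stage) the number of individuals that succeeded (numerator) out
#' of those tested (denominator), where stages are pretraining and the two
#' learning tasks. Totals are sums over groups; percentages are rounded
#' half-up to integer percent, and a zero denominator yields an undefined
#' (NA) percentage rather than zero.
#'
#' @param outcomes optional data.frame from [scoreTrialLog()] (columns group,
#'   task, reached_criterion): supplies the associative / reversal stages.
#' @param pretraining optional data.frame with columns group and success
#'   (0/1), one row per fish entering pretraining.
#' @return List with `cells` (group, stage, numerator, denominator,
#'   percentage) and `totals` (stage, numerator, denominator, percentage).
#' @examples
#' pre <- data.frame(group = rep(c("P1", "P2"), c(5, 4)),
#'                   success = c(1, 1, 1, 0, 1, 1, 1, 1, 1))
#' aggregateCounts(pretraining = pre)$totals
#' @export
aggregateCounts <- function(outcomes = NULL, pretraining = NULL) {
  pieces <- list()
  if (!is.null(pretraining)) {
    stopifnot(all(c("group", "success") %in% names(pretraining)))
    pieces$pretraining <- data.frame(
      group = pretraining$group,
      stage = rep("pretraining", nrow(pretraining)),
      ok = as.numeric(pretraining$success))
  }
  if (!is.null(outcomes)) {
    stopifnot(all(c("group", "task", "reached_criterion") %in%
                    names(outcomes)))
    pieces$tasks <- data.frame(group = outcomes$group,
                               stage = outcomes$task,
                               ok = as.numeric(outcomes$reached_criterion))
  }
  stages <- c("pretraining", "associative", "reversal")
  if (!length(pieces)) {
    empty <- data.frame(group = character(), stage = character(),
                        numerator = numeric(), denominator = numeric(),
                        percentage = numeric())
    return(list(cells = empty,
                totals = data.frame(stage = character(),
                                    numerator = numeric(),
                                    denominator = numeric(),
                                    percentage = numeric())))
  }
  long <- do.call(rbind, pieces)
  emptyCells <- data.frame(group = character(), stage = character(),
                           numerator = numeric(), denominator = numeric(),
                           percentage = numeric())
  emptyTotals <- data.frame(stage = character(), numerator = numeric(),
                            denominator = numeric(), percentage = numeric())
  if (!nrow(long)) return(list(cells = emptyCells, totals = emptyTotals))
  groups <- unique(long$group)
  grid <- expand.grid(group = groups,
                      stage = intersect(stages, unique(long$stage)),
                      stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sub <- long[long$group == grid$group[i] & long$stage == grid$stage[i], ]
    num <- sum(sub$ok)
    den <- nrow(sub)
    data.frame(group = grid$group[i], stage = grid$stage[i],
               numerator = num, denominator = den,
               percentage = if (den > 0) .roundHalfUp(100 * num / den)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  totals <- do.call(rbind, lapply(unique(cells$stage), function(st) {
    sub <- cells[cells$stage == st, ]
    num <- sum(sub$numerator)
    den <- sum(sub$denominator)
    data.frame(stage = st, numerator = num, denominator = den,
               percentage = if (den > 0) .roundHalfUp(100 * num / den)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(cells = cells, totals = totals)
}
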