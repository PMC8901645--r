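# Domain types and file formats for longitudinal claims.
#
# A patient record is a list:
#   patient_id (chr), gender ("M"|"F"|"U"), birth_year (int),
#   visits: list of visit; each visit a list:
#     date (int, days since 1970-01-01), type ("IP"|"OP"|"RX"),
#     dx / px / rx: character vectors of codes (set semantics per channel).
# Optional: label (0/1) on labelled records.
#
# On disk a corpus is JSON-lines, one patient object per line, with ISO-8601
# dates; see read_claims()/write_claims().

CHANNELS <- c("DIAG", "PROC", "DRUG")
CHANNEL_FIELDS <- c(DIAG = "dx", PROC = "px", DRUG = "rx")
VISIT_TYPES <- c("IP", "OP", "RX")
OOV_CODE <- "<OOV>"

#' Construct and validate a visit
#'
#' @param date Service date: a `Date`, an ISO-8601 string, or integer days
#'   since 1970-01-01.
#' @param type Visit type, one of `"IP"`, `"OP"`, `"RX"`.
#' @param dx,px,rx Character vectors of diagnosis / procedure / medication
#'   codes; duplicates within a channel are dropped. At least one code across
#'   the three channels is required.
#' @return A `claims_visit` list.
#' @export
visit <- function(date, type, dx = character(), px = character(), rx = character()) {
  if (is.character(date)) date <- date_to_days(date)
  date <- as.integer(date)
  if (!type %in% VISIT_TYPES)
    stop("unknown visit_type '", type, "' (expected IP, OP or RX)")
  dx <- unique(as.character(dx)); px <- unique(as.character(px)); rx <- unique(as.character(rx))
  if (length(dx) + length(px) + length(rx) == 0L)
    stop("visit must carry at least one medical code")
  if (any(!nzchar(c(dx, px, rx)))) stop("empty code string in visit")
  structure(list(date = date, type = type, dx = dx, px = px, rx = rx),
            class = "claims_visit")
}

#' Construct and validate a patient record
#'
#' Visits are re-sorted by service date (stable, so visits sharing a date
#' keep their input order).
#'
#' @param patient_id Opaque identifier string.
#' @param gender `"M"`, `"F"` or `"U"`.
#' @param birth_year Integer year of birth.
#' @param visits List of [visit()] objects, at least one.
#' @param label Optional binary outcome label (0/1) or `NULL`.
#' @return A `patient_record` list.
#' @export
patient_record <- function(patient_id, gender, birth_year, visits, label = NULL) {
  if (!is.character(patient_id) || !nzchar(patient_id))
    stop("patient_id must be a non-empty string")
  if (!gender %in% c("M", "F", "U"))
    stop("record ", patient_id, ": gender must be M, F or U")
  if (length(visits) == 0L)
    stop("record ", patient_id, ": empty visit list")
  dates <- vapply(visits, `[[`, integer(1), "date")
  ord <- order(dates)            # stable sort: same-date visits keep order
  structure(list(patient_id = patient_id, gender = gender,
                 birth_year = as.integer(birth_year),
                 visits = visits[ord], label = label),
            class = "patient_record")
}

visit_dates <- function(record) vapply(record$visits, `[[`, integer(1), "date")

#' Age (in years) at the first visit
#' @param record A `patient_record`.
#' @return Numeric age in years, floored at 0.
#' @export
age_at_first_visit <- function(record) {
  first_year <- as.integer(format(days_to_date(record$visits[[1]]$date), "%Y"))
  max(0, first_year - record$birth_year)
}

# ---------------------------------------------------------------------------
# JSONL claims format

parse_claims_line <- function(line, lineno) {
  obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                  error = function(e) stop("line ", lineno, ": invalid JSON (",
                                           conditionMessage(e), ")", call. = FALSE))
  for (f in c("patient_id", "gender", "birth_year", "visits"))
    if (is.null(obj[[f]]))
      stop("line ", lineno, ": missing required field '", f, "'", call. = FALSE)
  vs <- lapply(obj$visits, function(v) {
    for (f in c("date", "type"))
      if (is.null(v[[f]]))
        stop("line ", lineno, ": visit missing required field '", f, "'", call. = FALSE)
    visit(date = v$date, type = v$type,
          dx = unlist(v$dx) %||% character(),
          px = unlist(v$px) %||% character(),
          rx = unlist(v$rx) %||% character())
  })
  tryCatch(
    patient_record(obj$patient_id, obj$gender, obj$birth_year, vs,
                   label = if (!is.null(obj$label)) as.integer(obj$label)),
    error = function(e) stop("line ", lineno, ": ", conditionMessage(e), call. = FALSE))
}

#' Read a JSON-lines claims file
#'
#' One patient per line with fields `patient_id`, `gender`, `birth_year`,
#' `visits` (array of `{date, type, dx, px, rx}`) and an optional binary
#' `label`. Visits are re-sorted by date on load; malformed lines raise an
#' error naming the line and the offending field.
#'
#' @param path Path to a `.jsonl` claims file.
#' @return List of `patient_record`s in file order.
#' @seealso [write_claims()]
#' @export
read_claims <- function(path) {
  if (!file.exists(path)) stop("claims file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) out[[i]] <- parse_claims_line(lines[[i]], i)
  out
}

record_to_json <- function(r) {
  visits <- lapply(r$visits, function(v)
    list(date = format(days_to_date(v$date)), type = v$type,
         dx = as.list(v$dx), px = as.list(v$px), rx = as.list(v$rx)))
  obj <- list(patient_id = r$patient_id, gender = r$gender,
              birth_year = r$birth_year, visits = visits)
  if (!is.null(r$label)) obj$label <- r$label
  jsonlite::toJSON(obj, auto_unbox = TRUE)
}

#' Write records as a JSON-lines claims file
#'
#' Inverse of [read_claims()]: a written corpus reads back field-for-field
#' identical (dates to day resolution, code sets in order).
#'
#' @param records List of `patient_record`s (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records) writeLines(record_to_json(r), con, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Vocabulary

#' Build a code vocabulary from a corpus
#'
#' Codes with corpus frequency below `min_count` are excluded and map to the
#' reserved out-of-vocabulary token. Indices are dense per channel, assigned
#' in frequency-descending order with lexicographic tie-break, so the same
#' corpus always yields the same vocabulary; the OOV token takes the last
#' index of each channel.
#'
#' @param records List of `patient_record`s.
#' @param min_count Minimum corpus frequency for a code to get its own index
#'   (default 5; rare codes collapse into OOV rather than being dropped, so
#'   visit non-emptiness is preserved downstream).
#' @return A `code_vocabulary`: per channel, a named integer vector of
#'   0-based dense indices (including `"<OOV>"`).
#' @export
build_vocabulary <- function(records, min_count = 5L) {
  stopifnot(min_count >= 0)
  channels <- lapply(CHANNEL_FIELDS, function(field) {
    counts <- table(unlist(lapply(records, function(r)
      unlist(lapply(r$visits, `[[`, field)))))
    if (length(counts)) {
      keep <- counts[counts >= max(min_count, 1L)]
      # frequency-descending, ties broken by code string
      ord <- order(-as.integer(keep), names(keep), method = "radix")
      codes <- names(keep)[ord]
    } else codes <- character()
    idx <- seq_along(codes) - 1L
    names(idx) <- codes
    c(idx, stats::setNames(length(codes), OOV_CODE))
  })
  names(channels) <- CHANNELS
  structure(list(channels = channels), class = "code_vocabulary")
}

vocab_size <- function(vocab, channel = NULL) {
  if (is.null(channel)) sum(vapply(vocab$channels, length, integer(1)))
  else length(vocab$channels[[channel]])
}

# 0-based per-channel index of a code vector; unknown codes -> OOV index
vocab_index <- function(vocab, channel, codes) {
  tab <- vocab$channels[[channel]]
  i <- tab[codes]
  i[is.na(i)] <- tab[[OOV_CODE]]
  unname(i)
}

# 0-based global (cross-channel) code index: channels are concatenated in
# CHANNELS order. The NVP softmax runs over this combined space |C|.
vocab_global_index <- function(vocab, channel, codes) {
  off <- c(0L, cumsum(vapply(vocab$channels, length, integer(1))))[match(channel, CHANNELS)]
  off + vocab_index(vocab, channel, codes)
}

#' Write / read a vocabulary TSV
#'
#' Three tab-separated columns `channel`, `code`, `index` with a header line;
#' written and re-read bit-exactly.
#'
#' @param vocab A `code_vocabulary`.
#' @param path File path.
#' @return `read_vocabulary` returns a `code_vocabulary`; `write_vocabulary`
#'   returns `path` invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  rows <- unlist(lapply(CHANNELS, function(ch) {
    tab <- vocab$channels[[ch]]
    sprintf("%s\t%s\t%d", ch, names(tab), tab)
  }))
  writeLines(c("channel\tcode\tindex", rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character", "integer"),
                          quote = "", comment.char = "")
  channels <- lapply(CHANNELS, function(ch) {
    sub <- df[df$channel == ch, , drop = FALSE]
    sub <- sub[order(sub$index), , drop = FALSE]
    stats::setNames(sub$index, sub$code)
  })
  names(channels) <- CHANNELS
  structure(list(channels = channels), class = "code_vocabulary")
}

vocab_fingerprint <- function(vocab) {
  tf <- tempfile(); on.exit(unlink(tf))
  write_vocabulary(vocab, tf)
  fnv1a32(paste(readLines(tf), collapse = "\n"))
}

# ---------------------------------------------------------------------------
# Category grouper

OOV_CATEGORY <- "<OOV>"

#' Build a category grouper from a code-to-category table
#'
#' The grouper maps every (channel, code) pair to exactly one category
#' identifier (a CCS-like grouping for diagnoses/procedures, a drug-class
#' grouping for medications). Codes absent from the table map to a reserved
#' OOV category per channel.
#'
#' @param df Data frame with character columns `channel`, `code`, `category`.
#' @return A `category_grouper`.
#' @export
category_grouper <- function(df) {
  stopifnot(all(c("channel", "code", "category") %in% names(df)))
  if (anyDuplicated(paste(df$channel, df$code)))
    stop("grouper maps some (channel, code) to more than one category")
  maps <- lapply(CHANNELS, function(ch) {
    sub <- df[df$channel == ch, , drop = FALSE]
    stats::setNames(as.character(sub$category), sub$code)
  })
  names(maps) <- CHANNELS
  cats <- lapply(CHANNELS, function(ch) {
    lv <- sort(unique(maps[[ch]]))
    stats::setNames(seq_along(c(lv, OOV_CATEGORY)) - 1L, c(lv, OOV_CATEGORY))
  })
  names(cats) <- CHANNELS
  structure(list(maps = maps, categories = cats), class = "category_grouper")
}

#' Map a code to its category
#'
#' @param grouper A `category_grouper`.
#' @param channel `"DIAG"`, `"PROC"` or `"DRUG"`.
#' @param code Character vector of codes.
#' @return Character vector of category identifiers; codes absent from the
#'   grouper map to the OOV category.
#' @examples
#' g <- category_grouper(data.frame(channel = "DIAG", code = "493.00",
#'                                  category = "CCS:28"))
#' map_code_to_category(g, "DIAG", "493.00")
#' @export
map_code_to_category <- function(grouper, channel, code) {
  out <- grouper$maps[[channel]][code]
  out[is.na(out)] <- OOV_CATEGORY
  unname(out)
}

n_categories <- function(grouper, channel = NULL) {
  if (is.null(channel)) sum(vapply(grouper$categories, length, integer(1)))
  else length(grouper$categories[[channel]])
}

# 0-based global category index across channels (CHANNELS order)
category_global_index <- function(grouper, channel, codes) {
  off <- c(0L, cumsum(vapply(grouper$categories, length, integer(1))))[match(channel, CHANNELS)]
  cat <- map_code_to_category(grouper, channel, codes)
  idx <- grouper$categories[[channel]][cat]
  idx[is.na(idx)] <- grouper$categories[[channel]][[OOV_CATEGORY]]
  off + unname(idx)
}

#' Write / read a grouper TSV
#'
#' Three tab-separated columns `channel`, `code`, `category` with a header.
#'
#' @param grouper A `category_grouper`.
#' @param path File path.
#' @export
write_grouper <- function(grouper, path) {
  rows <- unlist(lapply(CHANNELS, function(ch) {
    m <- grouper$maps[[ch]]
    if (!length(m)) return(character())
    sprintf("%s\t%s\t%s", ch, names(m), m)
  }))
  writeLines(c("channel\tcode\tcategory", rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_grouper
#' @export
read_grouper <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "", comment.char = "")
  category_grouper(df)
}

grouper_fingerprint <- function(grouper) {
  tf <- tempfile(); on.exit(unlink(tf))
  write_grouper(grouper, tf)
  fnv1a32(paste(readLines(tf), collapse = "\n"))
}

# ---------------------------------------------------------------------------
# Cohort selection

#' Select a case/control cohort with index-event truncation
#'
#' Cases are patients with at least one visit flagged by `case_predicate`;
#' they are labelled 1 and truncated to the visits strictly before the first
#' flagged visit. Cases whose first flagged visit is their first visit have
#' no usable history and are dropped (counted in the `dropped_cases`
#' attribute). Controls are sampled uniformly without replacement from the
#' never-flagged patients at `control_ratio` controls per retained case,
#' labelled 0, keeping all visits up to the last recorded. The output order
#' is shuffled by `seed`.
#'
#' @param records List of `patient_record`s.
#' @param case_predicate Function `visit -> logical(1)` flagging index-event
#'   visits.
#' @param control_ratio Controls sampled per retained case (default 2).
#' @param seed Integer seed controlling control sampling and shuffling.
#' @param max_cases Optional cap on the number of cases (the first
#'   `max_cases` eligible cases in record order are kept), for cohort
#'   designs that fix the case count.
#' @return A `labeled_cohort`: list of `list(record, label)` with attributes
#'   `dropped_cases`, `n_cases`, `n_controls`.
#' @export
select_cohort <- function(records, case_predicate, control_ratio = 2, seed = 1L,
                          max_cases = Inf) {
  stopifnot(control_ratio > 0, max_cases >= 1)
  flags <- lapply(records, function(r)
    vapply(r$visits, function(v) isTRUE(case_predicate(v)), logical(1)))
  is_case <- vapply(flags, any, logical(1))
  if (!any(is_case)) stop("no case patients found by case_predicate")
  if (all(is_case)) stop("no eligible control patients (every record has an event)")

  dropped <- 0L
  positives <- list()
  for (i in which(is_case)) {
    if (length(positives) >= max_cases) break
    first_event <- which(flags[[i]])[1]
    if (first_event == 1L) { dropped <- dropped + 1L; next }
    r <- records[[i]]
    trunc <- patient_record(r$patient_id, r$gender, r$birth_year,
                            r$visits[seq_len(first_event - 1L)])
    positives[[length(positives) + 1L]] <- list(record = trunc, label = 1L)
  }
  if (length(positives) == 0L)
    stop("zero cases remain after truncation (", dropped, " dropped)")

  n_controls <- as.integer(round(control_ratio * length(positives)))
  pool <- which(!is_case)
  if (n_controls > length(pool))
    stop("control_ratio demands ", n_controls, " controls but only ",
         length(pool), " eligible patients exist")
  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  out <- withr_seed({
    ctrl_idx <- pool[sample.int(length(pool), n_controls)]
    negatives <- lapply(records[ctrl_idx], function(r) list(record = r, label = 0L))
    all <- c(positives, negatives)
    all[sample.int(length(all))]
  })
  structure(out, class = "labeled_cohort", dropped_cases = dropped,
            n_cases = length(positives), n_controls = n_controls)
}

cohort_labels <- function(cohort) vapply(cohort, `[[`, integer(1), "label")
cohort_records <- function(cohort) lapply(cohort, `[[`, "record")

#' Attach simulator labels as a labelled cohort
#'
#' Convenience for corpora whose records already carry a binary `label`
#' field (e.g. simulator output without an implanted index event).
#'
#' @param records List of `patient_record`s with `label` set.
#' @return A `labeled_cohort`.
#' @export
cohort_from_labels <- function(records) {
  has <- vapply(records, function(r) !is.null(r$label), logical(1))
  if (!all(has)) stop(sum(!has), " records carry no label")
  structure(lapply(records, function(r) list(record = r, label = as.integer(r$label))),
            class = "labeled_cohort",
            dropped_cases = 0L,
            n_cases = sum(vapply(records, `[[`, integer(1), "label") == 1L),
            n_controls = sum(vapply(records, `[[`, integer(1), "label") == 0L))
}
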