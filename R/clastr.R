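# Cellosaurus CLASTR client.
#
# CLASTR (https://www.cellosaurus.org/str-search/) scores a query STR
# profile against the published cell line profiles in Cellosaurus. The
# client builds the JSON query document, submits it with bounded retry, and
# renders ranked hits to an Excel workbook with hyperlinks to the matched
# cell line pages. Unit tests replay recorded-format fixtures offline; live
# queries are an explicit opt-in.

clastr_default_endpoint <- "https://www.cellosaurus.org/str-search/api/query"

# canonical name -> the vocabulary the CLASTR API expects
clastr_marker_vocabulary <- function() {
  markers <- c(
    "Amelogenin", "CSF1PO", "D1S1656", "D2S441", "D2S1338", "D3S1358",
    "D5S818", "D6S1043", "D7S820", "D8S1179", "D10S1248", "D12S391",
    "D13S317", "D16S539", "D18S51", "D19S433", "D21S11", "D22S1045",
    "DXS101", "DYS391", "F13A01", "F13B", "FESFPS", "FGA", "LPL",
    "Penta C", "Penta D", "Penta E", "SE33", "TH01", "TPOX", "vWA"
  )
  c(stats::setNames(markers, marker_key(markers)),
    AMEL = "Amelogenin")  # the package's canonical name for the sex marker
}

clastr_algorithms <- c(tanabe = 1L, `masters-q` = 2L, `masters-r` = 3L)
clastr_scoring_modes <- c(common = 1L, query = 2L, reference = 3L)

#' Build a CLASTR query document
#'
#' Serializes one profile into the JSON body the CLASTR API accepts:
#' scoring options first, then one field per recognized marker with the
#' alleles comma-joined in canonical order. Markers the service does not
#' know are dropped; a profile with no recognized markers is an error.
#'
#' @param profile An `str_profile`.
#' @param algorithm `"tanabe"`, `"masters-q"` or `"masters-r"`.
#' @param scoring_mode `"common"` (non-empty markers), `"query"` or
#'   `"reference"` marker universes, as exposed by the service.
#' @param score_filter Minimum score (percentage) for returned hits.
#' @param max_results Cap on the number of hits.
#' @param include_amelogenin Score the sex-typing marker? Default `FALSE`.
#' @param panel An [str_panel()] configuration (supplies the alias table
#'   and amelogenin name).
#' @return A named list ready for JSON encoding.
#' @examples
#' p <- str_profile("S1", list(CSF1PO = c("11", "12"), AMEL = "X"))
#' build_clastr_payload(p)$CSF1PO  # "11,12"
#' @export
build_clastr_payload <- function(profile,
                                 algorithm = c("tanabe", "masters-q",
                                               "masters-r"),
                                 scoring_mode = c("common", "query",
                                                  "reference"),
                                 score_filter = 70,
                                 max_results = 200L,
                                 include_amelogenin = FALSE,
                                 panel = str_panel()) {
  algorithm <- match.arg(algorithm)
  scoring_mode <- match.arg(scoring_mode)
  stopifnot(score_filter >= 0, score_filter <= 100, max_results >= 1L)
  vocab <- clastr_marker_vocabulary()
  g <- profile$genotypes[lengths(profile$genotypes) > 0L]
  keys <- marker_key(names(g))
  known <- keys %in% names(vocab)
  if (!any(known)) {
    stop("profile '", profile$sample_id,
         "' has no CLASTR-recognized markers", call. = FALSE)
  }
  fields <- stats::setNames(
    vapply(g[known], paste, character(1), collapse = ","),
    unname(vocab[keys[known]]))
  fields <- fields[order(match(names(fields), unname(vocab)))]
  c(list(description = profile$sample_id,
         algorithm = unname(clastr_algorithms[algorithm]),
         scoringMode = unname(clastr_scoring_modes[scoring_mode]),
         scoreFilter = score_filter,
         includeAmelogenin = include_amelogenin,
         maxResults = as.integer(max_results),
         outputFormat = "JSON"),
    as.list(fields))
}

#' Submit a query to the CLASTR service
#'
#' POSTs the payload as JSON and returns the parsed response body. Transient
#' failures (429 and 5xx) are retried idempotently with exponential backoff;
#' persistent failures raise an error carrying the HTTP status.
#'
#' @param payload A document from [build_clastr_payload()].
#' @param endpoint Service URL (version-pinned default).
#' @param timeout Request timeout in seconds.
#' @param max_tries Total attempts including the first (default 3).
#' @param backoff Function of the attempt number giving the wait in seconds
#'   before that retry (default exponential, capped at 10 s).
#' @return The parsed JSON response (a list).
#' @export
submit_clastr_query <- function(payload,
                                endpoint = clastr_default_endpoint,
                                timeout = 30, max_tries = 3L,
                                backoff = function(i) min(2^i, 10)) {
  req <- httr2::request(endpoint)
  req <- httr2::req_body_json(req, payload, auto_unbox = TRUE)
  req <- httr2::req_timeout(req, timeout)
  req <- httr2::req_user_agent(req, "strmatch R package")
  attempt <- 1L
  repeat {
    resp <- tryCatch(httr2::req_perform(req), error = function(e) e)
    if (!inherits(resp, "error")) {
      return(httr2::resp_body_json(resp))
    }
    # POSTing the same query is idempotent, so transient statuses and
    # connection failures are safe to retry
    transient <- inherits(resp, c("httr2_http_429", "httr2_http_503",
                                  "httr2_failure"))
    if (!transient || attempt >= max_tries) {
      stop(resp)
    }
    Sys.sleep(backoff(attempt))
    attempt <- attempt + 1L
  }
}

#' Parse a CLASTR response into a table of hits
#'
#' Extracts, for each matched cell line: the Cellosaurus accession (CVCL
#' id), name, similarity score, any problematic-line annotation, the
#' hyperlink to its Cellosaurus entry, and the per-marker allele sets the
#' service reported for the best-matching profile. Hits are ranked by
#' descending score. A response missing the `results` field (schema drift)
#' is an error naming the field.
#'
#' @param raw A parsed response list ([submit_clastr_query()] output or a
#'   recorded fixture read with [jsonlite::fromJSON] using
#'   `simplifyVector = FALSE`).
#' @return A tibble: `accession`, `name`, `score`, `problem`, `url`,
#'   `alleles` (list-column of named marker -> allele vectors).
#' @export
parse_clastr_response <- function(raw) {
  if (is.null(raw$results)) {
    stop("CLASTR response is missing field 'results'", call. = FALSE)
  }
  hits <- lapply(raw$results, function(h) {
    score <- h$bestScore %||% h$score
    for (f in c("accession", "name")) {
      if (is.null(h[[f]])) {
        stop("CLASTR hit is missing field '", f, "'", call. = FALSE)
      }
    }
    if (is.null(score)) {
      stop("CLASTR hit is missing field 'bestScore'", call. = FALSE)
    }
    acc <- as.character(h$accession)
    if (!grepl("^CVCL_[A-Z0-9]{4}$", acc)) {
      stop("accession '", acc, "' does not match the CVCL pattern",
           call. = FALSE)
    }
    tibble::tibble(
      accession = acc,
      name = as.character(h$name),
      score = as.numeric(score),
      problem = if (is.null(h$problem)) NA_character_
                else as.character(h$problem),
      url = paste0("https://www.cellosaurus.org/", acc),
      alleles = list(parse_clastr_hit_alleles(h))
    )
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out)) out <- out[order(-out$score, out$accession), ]
  out
}

# markers of the best-matching profile: [{name, alleles: [{value}...]}, ...]
parse_clastr_hit_alleles <- function(hit) {
  prof <- hit$profiles[[1]]
  if (is.null(prof)) return(list())
  g <- lapply(prof$markers, function(m)
    sort_alleles(vapply(m$alleles, function(a) as.character(a$value),
                        character(1))))
  stats::setNames(g, vapply(prof$markers, function(m)
    as.character(m$name), character(1)))
}

#' Write CLASTR hits to an Excel workbook
#'
#' One worksheet per query profile (sheet names are the sample ids,
#' sanitized to Excel's rules), hits ranked by descending score, with the
#' accession cell of each row hyperlinked to its Cellosaurus page.
#'
#' @param hits_per_query Named list: sample id -> hit tibble from
#'   [parse_clastr_response()].
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_clastr_excel <- function(hits_per_query, path) {
  stopifnot(is.list(hits_per_query), length(hits_per_query) >= 1L)
  sheets <- list()
  links <- list()
  for (id in names(hits_per_query)) {
    hits <- hits_per_query[[id]]
    tab <- tibble::tibble(
      accession = hits$accession,
      name = hits$name,
      score = round(as.numeric(hits$score), 2),
      problem = ifelse(is.na(hits$problem), "", hits$problem)
    )
    sheets[[id]] <- tab
    if (nrow(tab)) {
      links[[id]] <- data.frame(row = seq_len(nrow(tab)), col = 1L,
                                target = hits$url)
    }
  }
  write_xlsx(sheets, path, hyperlinks = links)
}
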