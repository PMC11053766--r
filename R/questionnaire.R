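#' Load a questionnaire definition by abbreviation
#'
#' Looks for \code{<abbreviation>.json} in the questionnaire folder.  Schema:
#' \code{{"abbreviation": "TLX", "items": [{"id", "prompt",
#' "scale": {"min", "max", "low_label", "high_label"}}]}}.  Items are kept in
#' file order.  A NASA-TLX definition ships with the package under
#' \code{inst/extdata/questionnaires}.
#'
#' @param abbreviation questionnaire short name, e.g. "TLX"
#' @param folder folder holding the JSON definitions (default: the shipped
#'   set)
#' @return a \linkS4class{Questionnaire}
#' @examples
#' q <- loadQuestionnaire("TLX")
#' nrow(q@items)
#' @export
loadQuestionnaire <- function(abbreviation,
                              folder = system.file("extdata",
                                                   "questionnaires",
                                                   package = "focalsim")) {
  path <- file.path(folder, paste0(abbreviation, ".json"))
  if (!file.exists(path))
    stop("no questionnaire file for abbreviation '", abbreviation, "' in ",
         folder)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- do.call(rbind, lapply(raw$items, function(it)
    data.frame(id = as.character(it$id), prompt = as.character(it$prompt),
               scale_min = as.numeric(it$scale$min %||% 0),
               scale_max = as.numeric(it$scale$max %||% 100),
               low_label = as.character(it$scale$low_label %||% ""),
               high_label = as.character(it$scale$high_label %||% ""),
               stringsAsFactors = FALSE)))
  new("Questionnaire", abbreviation = as.character(raw$abbreviation),
      items = items)
}

#' Record questionnaire answers as a timestamped CSV
#'
#' @param questionnaire a \linkS4class{Questionnaire}
#' @param answers named vector (names = item ids); every name must be a
#'   known item id
#' @param out_dir output folder (created if missing)
#' @return the path written
#' @export
recordAnswers <- function(questionnaire, answers, out_dir) {
  stopifnot(is(questionnaire, "Questionnaire"))
  unknown <- setdiff(names(answers), questionnaire@items$id)
  if (length(unknown))
    stop("answers for unknown item id(s): ", paste(unknown, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- timestampedPath(out_dir, "answers")
  df <- data.frame(item_id = names(answers),
                   response = unname(unlist(answers)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Read back recorded answers
#'
#' @param path CSV written by \code{\link{recordAnswers}}
#' @return named numeric/character vector of responses keyed by item id
#' @export
readAnswers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$response, df$item_id)
}
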