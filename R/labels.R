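#' Entity categories of the medication extraction task
#'
#' The seven categories handled by every layer of the pipeline: two drug
#' categories (`medication_name`, `medication_class`) and five attributes of
#' a drug mention (`dosage`, `frequency`, `duration`, `route`, `condition`).
#' The order is fixed and shared by all serializations and feature encodings.
#'
#' @return Character vector of the 7 category names, in canonical order.
#' @export
#' @examples
#' med_labels()
med_labels <- function() {
  c("medication_name", "medication_class", "dosage", "frequency",
    "duration", "route", "condition")
}

#' IOB tag inventory
#'
#' The 15 tags of the IOB scheme over [med_labels()]: `O` first, then `B-c`
#' and `I-c` for each category `c` in canonical order. This order defines
#' the one-hot rule-feature encoding and the tagger's output layer.
#'
#' @return Character vector of 15 tags.
#' @export
med_tags <- function() {
  labs <- med_labels()
  c("O", as.vector(rbind(paste0("B-", labs), paste0("I-", labs))))
}

#' @return integer index of `tags` into [med_tags()]; errors on unknown tags.
#' @noRd
tag_index <- function(tags) {
  idx <- match(tags, med_tags())
  if (anyNA(idx)) {
    stop("unknown IOB tag(s): ", paste(unique(tags[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Strip the B-/I- prefix, keeping O as O
#' @noRd
tag_class <- function(tags) {
  sub("^[BI]-", "", tags)
}

#' B/I prefix of a tag vector ("O" for O)
#' @noRd
tag_prefix <- function(tags) {
  ifelse(tags == "O", "O", substr(tags, 1L, 1L))
}

check_labels <- function(labels) {
  bad <- setdiff(labels, med_labels())
  if (length(bad) > 0) {
    stop("unknown label(s): ", paste(unique(bad), collapse = ", "))
  }
  invisible(labels)
}

#' Validate an IOB tag sequence against the tag grammar
#'
#' @param tags character vector of tags.
#' @return `TRUE` invisibly; errors if any tag is not in [med_tags()].
#' @export
validate_iob <- function(tags) {
  tag_index(tags)
  invisible(TRUE)
}

# empty span table with canonical columns
empty_spans <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             source = character(), text = character(),
             stringsAsFactors = FALSE)
}

# substring with 0-based half-open offsets
substr0 <- function(x, start, end) {
  substring(x, start + 1L, end)
}
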