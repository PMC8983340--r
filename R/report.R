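## Report rendering: lossless JSON, TSV with a printed-precision column, and
## markdown tables for human review.

#' Render scoring results as JSON, TSV or markdown
#'
#' Accepts a `bsa_breakdown`, a `bcc_breakdown`, or any result data frame
#' (ranked combinations, gap predictions, nominations, overlap counts). JSON
#' is lossless (full precision); TSV carries full-precision score columns plus
#' a `*_display` companion at printed precision; markdown is a table for human
#' review. Empty result sets render as valid empty documents.
#'
#' @param results The object to render.
#' @param format One of `"json"`, `"tsv"`, `"markdown"`.
#' @param path Optional file to write to.
#' @param precision Printed precision for display columns (default 1).
#' @return The rendered document as a character scalar (invisibly when `path`
#'   is given).
#' @export
render_report <- function(results, format = c("json", "tsv", "markdown"),
                          path = NULL, precision = 1) {
  format <- match.arg(format)
  df <- as_report_frame(results)
  doc <- switch(format,
    json = jsonlite::toJSON(report_payload(results), auto_unbox = TRUE,
                            digits = NA, pretty = TRUE, null = "null"),
    tsv = render_tsv(df, precision),
    markdown = render_markdown(df, precision)
  )
  doc <- as.character(doc)
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

report_payload <- function(results) {
  if (inherits(results, "bsa_breakdown")) {
    list(drug_id = results$drug_id, virus_id = results$virus_id,
         components = as.list(results$components), total = results$total,
         provenance = results$provenance)
  } else if (inherits(results, "bcc_breakdown")) {
    list(drug_1 = results$pair[1], drug_2 = results$pair[2],
         virus_id = results$virus_id,
         k_di = results$k_di, k_dti = results$k_dti,
         k_drs = results$k_drs, k_roa = results$k_roa,
         bsa_sum = results$bsa_sum, bcc_score = results$bcc_score,
         delta = results$delta, effective = results$effective,
         target_class = results$target_class, provenance = results$provenance)
  } else {
    results
  }
}

as_report_frame <- function(results) {
  if (inherits(results, "bsa_breakdown")) {
    cbind(data.frame(drug_id = results$drug_id, virus_id = results$virus_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(results$components)),
          data.frame(total = results$total))
  } else if (inherits(results, "bcc_breakdown")) {
    data.frame(drug_1 = results$pair[1], drug_2 = results$pair[2],
               virus = results$virus_id, k_di = results$k_di,
               k_dti = results$k_dti, k_drs = results$k_drs,
               k_roa = results$k_roa, bsa_sum = results$bsa_sum,
               bcc_score = results$bcc_score, delta = results$delta,
               effective = results$effective,
               target_class = results$target_class, stringsAsFactors = FALSE)
  } else {
    as.data.frame(results)
  }
}

.display_columns <- c("total", "bsa_sum", "bcc_score", "delta")

render_tsv <- function(df, precision) {
  for (cl in intersect(.display_columns, names(df))) {
    df[[paste0(cl, "_display")]] <- display_score(df[[cl]], precision)
  }
  con <- textConnection("out", open = "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

render_markdown <- function(df, precision) {
  cells <- df
  for (cl in names(cells)) {
    if (is.numeric(cells[[cl]]) && cl %in% .display_columns) {
      cells[[cl]] <- display_score(cells[[cl]], precision)
    } else {
      cells[[cl]] <- as.character(cells[[cl]])
    }
  }
  header <- paste0("| ", paste(names(cells), collapse = " | "), " |")
  rule <- paste0("|", paste(rep(" --- ", ncol(cells)), collapse = "|"), "|")
  if (!nrow(cells)) return(paste(header, rule, sep = "\n"))
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, rule, rows), collapse = "\n")
}
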