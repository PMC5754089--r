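#' Serialize a test result as a JSON report
#'
#' Writes every field of a `pks_result`, `ks2_result` or `lr_result`, plus any
#' provenance supplied (input file, burn-in, seed, ...), as a JSON object so
#' that a run can be reproduced from its report.
#'
#' @param result a test result object.
#' @param path output path.
#' @param provenance optional named list appended under `"provenance"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, provenance = NULL) {
  if (!inherits(result, c("pks_result", "ks2_result", "lr_result")))
    stop("'result' must be a pks_result, ks2_result or lr_result")
  obj <- list(schema = "ksclock-report-1",
              kind = class(result)[1L],
              result = unclass(result))
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
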