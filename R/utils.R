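# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# md5 of the canonical JSON form of a config list (base tools only)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Frequency and percentage of a categorical variable
#'
#' Describes a categorical variable the way cohort tables report it:
#' raw counts with percentages of the column total.
#'
#' @param x a factor or character vector (NAs dropped with a count).
#' @param digits decimal places for the percentage (default 1).
#' @return a data.frame with columns `level`, `n`, `pct`.
#' @examples
#' frequency_table(rep(c("female", "male"), c(25, 45)))
#' @export
frequency_table <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  nc_assert(length(x) > 0, "no non-missing values")
  tab <- table(x)
  data.frame(level = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(x), digits),
             row.names = NULL, stringsAsFactors = FALSE)
}
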