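#' Read measurement records from CSV
#'
#' Expects columns `user_id`, `date`, `sbp`, `dbp`, `pulse`. Dates are
#' parsed as ISO-8601 days; rows with unparseable dates or non-positive
#' vitals are rejected, with the offending line numbers and a count
#' reported via [message()].
#'
#' @param path CSV path.
#' @return data.frame with `date` as `Date`; possibly zero rows.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  need <- c("user_id", "date", "sbp", "dbp", "pulse")
  miss <- setdiff(need, names(df))
  stop_if_not(length(miss) == 0, "missing required column(s): ",
              paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(empty_measurements())
  date <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  vit <- suppressWarnings(cbind(as.numeric(df$sbp), as.numeric(df$dbp),
                                as.numeric(df$pulse)))
  bad <- is.na(date) | apply(is.na(vit) | vit <= 0, 1, any)
  if (any(bad)) {
    message(sum(bad), " row(s) rejected (bad date or non-positive vitals): lines ",
            paste(utils::head(which(bad) + 1L, 20L), collapse = ", "))
    df <- df[!bad, , drop = FALSE]; date <- date[!bad]
    vit <- vit[!bad, , drop = FALSE]
  }
  data.frame(user_id = df$user_id, date = date, sbp = vit[, 1],
             dbp = vit[, 2], pulse = vit[, 3], stringsAsFactors = FALSE)
}

#' Read user profiles from CSV
#'
#' Expects columns `user_id`, `birth_ym` ("YYYY-MM"), `sex`
#' (male/female/unspecified), `regime` (A/B). Rows with malformed
#' `birth_ym` or unknown sex levels are rejected with a message.
#'
#' @param path CSV path.
#' @return data.frame of profiles.
#' @export
read_users <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  need <- c("user_id", "birth_ym", "sex", "regime")
  miss <- setdiff(need, names(df))
  stop_if_not(length(miss) == 0, "missing required column(s): ",
              paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(empty_users())
  bad <- !grepl("^[0-9]{4}-[0-9]{2}$", df$birth_ym) |
    !df$sex %in% c("male", "female", "unspecified")
  if (any(bad)) {
    message(sum(bad), " user row(s) rejected: lines ",
            paste(utils::head(which(bad) + 1L, 20L), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  df[, need]
}
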