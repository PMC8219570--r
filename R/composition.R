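#' Read a body-composition table
#'
#' Reads the canonical CSV dialect
#' `id,sex,fatm_kg,smm_kg,height_cm,weight_kg,bmi,age,psych` (comma-separated,
#' UTF-8, header row; `psych` optional) into a validated data frame with
#' columns `id, sex, fatm, smm, height, weight, bmi, age, psych`. BMI is
#' recomputed from weight and height when both are present and cross-checked
#' against the stated value (relative tolerance 1e-3); rows failing any
#' invariant (negative fat mass, non-positive muscle mass, fat + muscle not
#' below weight, inconsistent BMI, unknown sex) are dropped with a
#' row-numbered warning.
#'
#' @param path CSV file.
#' @return data frame of composition records, one row per valid identity.
#' @export
read_composition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("id", "sex", "fatm_kg", "smm_kg")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stopf("schema error in %s: missing mandatory column(s) %s",
          path, paste(missing, collapse = ", "))
  opt <- function(col) if (col %in% names(df)) as.numeric(df[[col]])
                       else rep(NA_real_, nrow(df))
  out <- data.frame(
    id = as.character(df$id),
    sex = as.character(df$sex),
    fatm = as.numeric(df$fatm_kg),
    smm = as.numeric(df$smm_kg),
    height = opt("height_cm"),
    weight = opt("weight_kg"),
    bmi = opt("bmi"),
    age = opt("age"),
    psych = opt("psych"),
    stringsAsFactors = FALSE
  )
  if (!nrow(out)) {
    warnf("composition table %s is empty", path)
    return(out)
  }
  problems <- character()
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    msg <- validate_composition_row(r)
    if (!is.null(msg)) {
      keep[i] <- FALSE
      problems <- c(problems, sprintf("row %d (id %s): %s", i, r$id, msg))
    } else if (is.finite(r$height) && is.finite(r$weight)) {
      out$bmi[i] <- r$weight / (r$height / 100)^2
    }
  }
  if (length(problems))
    warnf("rejected %d row(s):\n  %s", length(problems),
          paste(problems, collapse = "\n  "))
  out[keep, , drop = FALSE]
}

# NULL if valid, else a message
validate_composition_row <- function(r) {
  if (!r$sex %in% c("male", "female")) return(sprintf("unknown sex '%s'", r$sex))
  if (!is.finite(r$fatm) || r$fatm < 0) return("fat mass must be >= 0 kg")
  if (!is.finite(r$smm) || r$smm <= 0) return("skeletal muscle mass must be > 0 kg")
  if (is.finite(r$height) && r$height <= 0) return("height must be > 0 cm")
  if (is.finite(r$weight) && r$weight <= 0) return("weight must be > 0 kg")
  if (is.finite(r$weight) && r$fatm + r$smm >= r$weight)
    return("fat + muscle mass must be below total weight")
  if (is.finite(r$height) && is.finite(r$weight) && is.finite(r$bmi)) {
    expected <- r$weight / (r$height / 100)^2
    if (abs(r$bmi - expected) > 1e-3 * expected)
      return(sprintf("stated BMI %.3f inconsistent with weight/height^2 = %.3f",
                     r$bmi, expected))
  }
  NULL
}

#' Write a composition table in the canonical CSV dialect
#'
#' @param records data frame as returned by [read_composition_table()] or
#'   [sample_composition()].
#' @param path output CSV file.
#' @export
write_composition_table <- function(records, path) {
  out <- data.frame(id = records$id, sex = records$sex,
                    fatm_kg = records$fatm, smm_kg = records$smm,
                    height_cm = records$height, weight_kg = records$weight,
                    bmi = records$bmi, age = records$age,
                    psych = records$psych)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
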