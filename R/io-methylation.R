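# Methylation inputs: sample sheet CSV and probes x samples beta matrix.

#' Read a methylation sample sheet
#'
#' CSV with columns `sample_id`, `strain`, `tissue`, `sex`, `age_days`.
#'
#' @param path CSV path.
#' @return Data frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  needed <- c("sample_id", "strain", "tissue", "sex", "age_days")
  miss <- setdiff(needed, names(meta))
  if (length(miss)) stop("sample sheet is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (any(meta$age_days < 0)) stop("negative age_days", call. = FALSE)
  meta
}

#' Read a beta-value matrix (probes x samples TSV)
#'
#' First column holds probe ids; remaining columns one sample each.
#' Non-missing values must lie in \[0, 1\].
#'
#' @param path TSV path.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, showProgress = FALSE)
  probes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, with = FALSE])
  mode(m) <- "double"
  rownames(m) <- probes
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta values outside [0, 1]", call. = FALSE)
  }
  m
}
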