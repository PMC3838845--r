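#' Read two-group test data from CSV
#'
#' Expects a header row with a binary `status` column (0 = non-diseased,
#' 1 = diseased), a continuous response `y`, and one column per covariate.
#' Column order is irrelevant; covariates are every column other than
#' `status` and `y`, in file order (or the subset/order named in
#' `covariates`).
#'
#' @param path CSV file path.
#' @param covariates optional character vector naming (and ordering) the
#'   covariate columns to use.
#' @return An uncentered [two_group_sample()].
#' @export
read_two_group_csv <- function(path, covariates = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("status", "y") %in% names(df))) {
    stop("CSV must contain 'status' and 'y' columns")
  }
  bad <- which(!(df$status %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary status value in data row ", bad[1],
         " (found ", df$status[bad[1]], ")")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), c("status", "y"))
  } else if (!all(covariates %in% names(df))) {
    stop("missing covariate column(s): ",
         paste(setdiff(covariates, names(df)), collapse = ", "))
  }
  if (length(covariates) == 0) stop("no covariate columns found")
  if (anyNA(df[, c("status", "y", covariates)])) {
    stop("NA cells are not allowed in the input")
  }
  nd <- df$status == 0
  if (sum(nd) < 2 || sum(!nd) < 2) {
    stop("each group needs at least 2 rows")
  }
  grab <- function(rows) {
    z <- as.matrix(df[rows, covariates, drop = FALSE])
    rownames(z) <- NULL
    z
  }
  two_group_sample(
    y_nondiseased = df$y[nd],
    y_diseased = df$y[!nd],
    z_nondiseased = grab(nd),
    z_diseased = grab(!nd)
  )
}

#' Write a two-group sample to CSV
#'
#' Inverse of [read_two_group_csv()]: columns `status`, `y`, then the
#' covariates (named `z1..zd` when unnamed). Values are written at full
#' double precision so a read-back round-trips.
#'
#' @param sample a [two_group_sample()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_sample_csv <- function(sample, path) {
  stopifnot(inherits(sample, "two_group_sample"))
  z <- rbind(sample$z_nondiseased, sample$z_diseased)
  if (is.null(colnames(z))) colnames(z) <- paste0("z", seq_len(ncol(z)))
  df <- data.frame(
    status = c(rep(0L, sample$n_nondiseased), rep(1L, sample$n_diseased)),
    y = c(sample$y_nondiseased, sample$y_diseased)
  )
  df <- cbind(df, as.data.frame(z))
  ok <- tryCatch({
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = ","), con)
    body <- apply(df, 1, function(row) {
      paste(vapply(row, function(v) format(as.numeric(v), digits = 17),
                   character(1)), collapse = ",")
    })
    writeLines(body, con)
    TRUE
  }, error = function(e) stop("cannot write fixture to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Generate and write a simulation fixture
#'
#' Draws one replicate of a simulation setting and writes it in the
#' [read_two_group_csv()] schema.
#'
#' @param setting_id 1, 2, or 3.
#' @param seed integer seed.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_fixture <- function(setting_id, seed, path) {
  setting <- make_setting(setting_id)
  smp <- generate_setting_data(setting, seed)
  write_sample_csv(smp, path)
}

#' DPOAE audiology data schema (loader stub)
#'
#' Documents the expected layout of the distortion-product otoacoustic
#' emissions hearing-test data: one row per selected ear with `status`
#' (1 = hearing impaired), `y` (negative signal-to-noise ratio), and centered
#' covariates frequency/100, intensity/10, (hearing threshold - 20)/10 plus
#' their two-way interactions. No data ship with the package; supply your own
#' extract in this schema.
#'
#' @param path CSV file in the schema above.
#' @return An uncentered [two_group_sample()].
#' @export
read_dpoae_csv <- function(path) {
  read_two_group_csv(path)
}
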