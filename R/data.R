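# Input validation and file reading for long-format ANCOVA data.

# Internal canonical form: a list with
#   group  integer index 1..G in first-appearance order of the labels
#   labels the original labels, one per group
#   y      numeric response
#   X      numeric matrix NT x P of covariates
validate_ancova_data <- function(data) {
  if (!is.data.frame(data)) stop("'data' must be a data.frame")
  nm <- names(data)
  if (!all(c("group", "y") %in% nm)) {
    stop("'data' must contain columns 'group' and 'y'")
  }
  xcols <- setdiff(nm, c("group", "y"))
  if (length(xcols) < 1) stop("'data' must contain at least one covariate column")
  for (cn in c("y", xcols)) {
    v <- data[[cn]]
    if (!is.numeric(v)) stop("column '", cn, "' must be numeric")
    if (anyNA(v)) {
      stop("missing values in column '", cn, "' at row(s): ",
           paste(which(is.na(v)), collapse = ", "))
    }
  }
  if (anyNA(data$group)) {
    stop("missing values in column 'group' at row(s): ",
         paste(which(is.na(data$group)), collapse = ", "))
  }
  labels <- unique(as.character(data$group))  # first-appearance order
  group <- match(as.character(data$group), labels)
  G <- length(labels)
  if (G < 2) stop("at least two groups are required")
  X <- as.matrix(data[xcols])
  storage.mode(X) <- "double"
  list(group = group, labels = labels, y = as.numeric(data$y), X = X,
       G = G, P = ncol(X), NT = nrow(data))
}

#' Read long-format ANCOVA data
#'
#' Reads a delimiter-separated table with a header row and columns
#' `group`, `y`, `x1`, ..., `xP` (one row per subject).  The group column
#' may hold arbitrary labels; groups are indexed in order of first
#' appearance, and contrast coefficients supplied elsewhere are matched to
#' that order.  Any missing value or non-numeric entry in a response or
#' covariate column is an error naming the offending rows.
#'
#' @param path path to the text file.
#' @param sep field separator (default comma).
#' @return a `data.frame` with columns `group`, `y` and the covariates,
#'   checked and ready for [fit_ancova()].
#' @export
read_ancova_data <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_ancova_data(df)  # errors propagate with row numbers
  df
}
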