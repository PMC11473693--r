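#' Construct an environmental table with variable metadata
#'
#' An `env_table` couples per-site environmental values with the variable
#' metadata needed downstream: the category of each variable (`natural`
#' abiotic gradient vs anthropogenic `threat`), the direction of benefit for
#' threats (`high_good`, e.g. connectivity, vs `low_good`, e.g. urbanisation)
#' and whether the column has been residualized against confounders.
#'
#' @param data Data frame with a `site_id` column plus one numeric column per
#'   variable. Missing values are not allowed.
#' @param metadata Data frame with columns `variable`, `category`
#'   (`"natural"` or `"threat"`), `direction` (`"high_good"`, `"low_good"` or
#'   `NA` for natural variables) and optionally `residualized` (logical,
#'   default `FALSE`). Must cover every variable column of `data`.
#'
#' @return An object of class `env_table` (a data frame with a `metadata`
#'   attribute).
#' @export
env_table <- function(data, metadata) {
  stopifnot(is.data.frame(data), is.data.frame(metadata))
  if (!"site_id" %in% names(data)) {
    stop("`data` must contain a `site_id` column.", call. = FALSE)
  }
  if (anyDuplicated(data$site_id)) {
    stop("`site_id` values must be unique.", call. = FALSE)
  }
  vars <- setdiff(names(data), "site_id")
  if (!all(vapply(data[vars], is.numeric, logical(1L)))) {
    stop("All variable columns must be numeric.", call. = FALSE)
  }
  if (anyNA(data[vars])) {
    stop("Environmental values must not contain missing values.", call. = FALSE)
  }
  if (!all(c("variable", "category", "direction") %in% names(metadata))) {
    stop("`metadata` needs columns variable, category, direction.", call. = FALSE)
  }
  if (is.null(metadata$residualized)) metadata$residualized <- FALSE
  missing_meta <- setdiff(vars, metadata$variable)
  if (length(missing_meta)) {
    stop("No metadata for variable(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(metadata$category, c("natural", "threat"))
  if (length(bad_cat)) {
    stop("Unknown category: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  bad_dir <- setdiff(metadata$direction[!is.na(metadata$direction)],
                     c("high_good", "low_good"))
  if (length(bad_dir)) {
    stop("Unknown direction: ", paste(bad_dir, collapse = ", "), call. = FALSE)
  }
  metadata <- metadata[match(vars, metadata$variable),
                       c("variable", "category", "direction", "residualized")]
  rownames(metadata) <- NULL
  structure(data, metadata = metadata, class = c("env_table", "data.frame"))
}

#' Variable names and metadata accessors
#'
#' @param env An `env_table`.
#' @return `env_variables()`: character vector of variable column names.
#'   `env_metadata()`: the metadata data frame. `natural_variables()` /
#'   `threat_variables()`: the variables in each category.
#' @export
env_variables <- function(env) {
  setdiff(names(env), "site_id")
}

#' @rdname env_variables
#' @export
env_metadata <- function(env) {
  attr(env, "metadata")
}

#' @rdname env_variables
#' @export
natural_variables <- function(env) {
  m <- env_metadata(env)
  m$variable[m$category == "natural"]
}

#' @rdname env_variables
#' @export
threat_variables <- function(env) {
  m <- env_metadata(env)
  m$variable[m$category == "threat"]
}

#' @export
`[.env_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "site_id" %in% names(out)) {
    meta <- attr(x, "metadata")
    attr(out, "metadata") <- meta[meta$variable %in% names(out), ,
                                  drop = FALSE]
    class(out) <- c("env_table", "data.frame")
  } else if (is.data.frame(out)) {
    class(out) <- "data.frame"
    attr(out, "metadata") <- NULL
  }
  out
}

#' @export
print.env_table <- function(x, ...) {
  m <- env_metadata(x)
  cat("Environmental table:", nrow(x), "sites,", nrow(m), "variables (",
      sum(m$category == "natural"), "natural /",
      sum(m$category == "threat"), "threat )\n")
  print.data.frame(utils::head(as.data.frame(x), 4L), digits = 3)
  if (nrow(x) > 4L) cat("...", nrow(x) - 4L, "more sites\n")
  invisible(x)
}

.check_variables <- function(env, vars, what = "variable") {
  missing <- setdiff(vars, env_variables(env))
  if (length(missing)) {
    stop("Unknown ", what, "(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
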