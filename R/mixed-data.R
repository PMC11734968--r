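#' Declare the variables of a mixed dataset
#'
#' A variable specification records, for every column of a dataset, whether it
#' is modelled on the Gaussian (continuous) or the categorical domain, the
#' admissible levels of categorical variables, and an optional display group
#' used when exporting tables (e.g. "lifestyle", "ageism").
#'
#' @param name Character vector of unique column names.
#' @param domain Character vector, each entry `"continuous"` or
#'   `"categorical"`, recycled to the length of `name`.
#' @param levels List of character vectors with the ordered levels of each
#'   categorical variable; continuous variables must have an empty level set.
#' @param display_group Optional character vector of free-form group labels.
#'
#' @return A tibble with columns `name`, `domain`, `levels` (list column) and
#'   `display_group`, of class `variable_spec`.
#' @export
#' @examples
#' variable_spec(
#'   name = c("MWB", "PND"),
#'   domain = c("continuous", "categorical"),
#'   levels = list(character(), c("none", "cancer", "other"))
#' )
variable_spec <- function(name, domain, levels = NULL, display_group = NA_character_) {
  name <- as.character(name)
  domain <- rep_len(as.character(domain), length(name))
  if (is.null(levels)) levels <- rep(list(character()), length(name))
  if (!is.list(levels)) levels <- list(levels)
  levels <- rep_len(levels, length(name))
  levels <- lapply(levels, as.character)
  spec <- tibble::tibble(
    name = name,
    domain = domain,
    levels = levels,
    display_group = rep_len(as.character(display_group), length(name))
  )
  validate_variable_spec(spec)
  class(spec) <- c("variable_spec", class(tibble::tibble()))
  spec
}

validate_variable_spec <- function(spec) {
  stopifnot(is.data.frame(spec), all(c("name", "domain", "levels") %in% names(spec)))
  if (anyDuplicated(spec$name)) {
    stop("variable names must be unique; duplicated: ",
         paste(unique(spec$name[duplicated(spec$name)]), collapse = ", "))
  }
  bad <- !spec$domain %in% c("continuous", "categorical")
  if (any(bad)) {
    stop("unknown domain for variable(s): ", paste(spec$name[bad], collapse = ", "))
  }
  nlev <- vapply(spec$levels, length, integer(1))
  if (any(spec$domain == "categorical" & nlev < 2)) {
    stop("categorical variables need at least 2 declared levels: ",
         paste(spec$name[spec$domain == "categorical" & nlev < 2], collapse = ", "))
  }
  if (any(spec$domain == "continuous" & nlev > 0)) {
    stop("continuous variables must not declare levels: ",
         paste(spec$name[spec$domain == "continuous" & nlev > 0], collapse = ", "))
  }
  invisible(spec)
}

#' Construct a validated mixed dataset
#'
#' Bundles an N x p table of observations with its [variable_spec()]. All
#' validation happens here: every column must be declared, categorical cells
#' must be declared levels, and no cell may be missing. Categorical columns
#' are stored as factors with the declared level order.
#'
#' @param values A data frame with one column per declared variable.
#' @param spec A [variable_spec()] aligned to the columns of `values`.
#'
#' @return An object of class `mixed_data`: a list with elements `data`
#'   (tibble), `spec` (the variable specification) and `n` (row count).
#' @export
mixed_data <- function(values, spec) {
  validate_variable_spec(spec)
  values <- tibble::as_tibble(values)
  undeclared <- setdiff(names(values), spec$name)
  if (length(undeclared)) {
    stop("undeclared column(s) in data: ", paste(undeclared, collapse = ", "))
  }
  missing_cols <- setdiff(spec$name, names(values))
  if (length(missing_cols)) {
    stop("column(s) declared in spec but absent from data: ",
         paste(missing_cols, collapse = ", "))
  }
  values <- values[spec$name]
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop("a mixed dataset needs N >= 1 rows and p >= 2 variables")
  }
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    col <- values[[nm]]
    if (anyNA(col)) {
      stop(sprintf("missing value in column '%s' (first at row %d)",
                   nm, which(is.na(col))[1]))
    }
    if (spec$domain[i] == "continuous") {
      if (!is.numeric(col)) {
        stop(sprintf("column '%s' is declared continuous but is not numeric", nm))
      }
    } else {
      col <- as.character(col)
      lev <- spec$levels[[i]]
      bad <- !col %in% lev
      if (any(bad)) {
        stop(sprintf("undeclared level '%s' in categorical column '%s' (first at row %d)",
                     col[which(bad)[1]], nm, which(bad)[1]))
      }
      values[[nm]] <- factor(col, levels = lev)
    }
  }
  structure(list(data = values, spec = spec, n = nrow(values)),
            class = "mixed_data")
}

#' @export
print.mixed_data <- function(x, ...) {
  cat(sprintf("<mixed_data> %d observations x %d variables (%d continuous, %d categorical)\n",
              x$n, nrow(x$spec),
              sum(x$spec$domain == "continuous"),
              sum(x$spec$domain == "categorical")))
  print(utils::head(x$data, 5))
  invisible(x)
}

#' @export
dim.mixed_data <- function(x) c(x$n, nrow(x$spec))

#' @rdname mixed_data
#' @param x A `mixed_data` object.
#' @param ... Unused.
#' @export
as_tibble.mixed_data <- function(x, ...) x$data

continuous_vars <- function(x) x$spec$name[x$spec$domain == "continuous"]
categorical_vars <- function(x) x$spec$name[x$spec$domain == "categorical"]

#' Read and write mixed tables
#'
#' `read_mixed_table()` reads a comma-separated data file together with a YAML
#' sidecar declaring each column's domain (and levels, for categorical
#' columns), and returns a validated [mixed_data()] with the original row
#' order. `write_mixed_table()` is its inverse; continuous columns are
#' serialized at full (17 significant digit) precision so a write/read
#' round-trip reproduces the values bit for bit.
#'
#' @param data_path Path to a CSV file with a header row.
#' @param spec_path Path to the YAML variable-specification sidecar.
#'
#' @return `read_mixed_table()` returns a `mixed_data`;
#'   `write_mixed_table()` invisibly returns its input.
#' @export
read_mixed_table <- function(data_path, spec_path) {
  spec <- read_variable_spec(spec_path)
  types <- ifelse(spec$domain == "continuous", "numeric", "character")
  # base strtod parsing is correctly rounded, so full-precision round-trips
  # reproduce doubles bit for bit
  values <- utils::read.csv(data_path, check.names = FALSE,
                            colClasses = stats::setNames(types, spec$name))
  mixed_data(tibble::as_tibble(values), spec)
}

#' @rdname read_mixed_table
#' @param x A `mixed_data` object to write.
#' @export
write_mixed_table <- function(x, data_path, spec_path) {
  stopifnot(inherits(x, "mixed_data"))
  out <- x$data
  for (nm in continuous_vars(x)) {
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  for (nm in categorical_vars(x)) {
    out[[nm]] <- as.character(out[[nm]])
  }
  readr::write_csv(out, data_path, progress = FALSE)
  write_variable_spec(x$spec, spec_path)
  invisible(x)
}

#' @rdname read_mixed_table
#' @param path Path to a YAML variable specification.
#' @export
read_variable_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  vars <- raw$variables
  if (is.null(vars)) stop("spec file has no 'variables' entry: ", path)
  variable_spec(
    name = vapply(vars, function(v) v$name, character(1)),
    domain = vapply(vars, function(v) v$domain, character(1)),
    levels = lapply(vars, function(v) as.character(v$levels %||% character())),
    display_group = vapply(vars, function(v) v$display_group %||% NA_character_,
                           character(1))
  )
}

#' @rdname read_mixed_table
#' @param spec A [variable_spec()].
#' @export
write_variable_spec <- function(spec, path) {
  vars <- lapply(seq_len(nrow(spec)), function(i) {
    v <- list(name = spec$name[i], domain = spec$domain[i])
    if (length(spec$levels[[i]])) v$levels <- as.list(spec$levels[[i]])
    if (!is.na(spec$display_group[i])) v$display_group <- spec$display_group[i]
    v
  })
  yaml::write_yaml(list(variables = vars), path)
  invisible(spec)
}

#' Robust MAD outlier flags
#'
#' Flags observations whose robust z-score exceeds a threshold. The robust
#' z-score is `|x - median(x)| / (1.4826 * MAD)` with
#' `MAD = median(|x - median(x)|)`; the constant 1.4826 makes the MAD a
#' consistent estimate of the standard deviation under normality. When the
#' MAD is zero the scale is degenerate and carries no outlier information:
#' no observation is flagged and a warning is emitted.
#'
#' @param values Numeric vector of at least two values.
#' @param threshold Positive robust z-score cutoff; defaults to 2.5.
#'
#' @return A logical vector of the same length as `values`.
#' @export
#' @examples
#' mad_outlier_flags(c(1, 2, 3, 4, 100))
mad_outlier_flags <- function(values, threshold = 2.5) {
  stopifnot(is.numeric(values), length(values) >= 2,
            is.numeric(threshold), threshold > 0)
  med <- stats::median(values)
  mad0 <- stats::median(abs(values - med))
  if (mad0 == 0) {
    warning("MAD is zero (degenerate scale); no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  abs(values - med) / (1.4826 * mad0) > threshold
}

#' Apply ordered exclusion rules to a dataset
#'
#' Exclusion rules are applied sequentially in their declared order; each
#' rule's removal count is taken against the rows that survived all earlier
#' rules, matching the way participant-flow diagrams report exclusions.
#' Optionally the first `select_first` surviving rows (in original order) are
#' then selected.
#'
#' @param x A [mixed_data()].
#' @param rules Named list of predicate functions; each receives the current
#'   data tibble and returns a logical vector marking rows to *remove*.
#' @param select_first Optional integer: keep only the first that many
#'   surviving rows.
#'
#' @return A list with elements `data` (the filtered `mixed_data`) and
#'   `report` (an `exclusion_report`).
#' @export
apply_exclusions <- function(x, rules = list(), select_first = NULL) {
  stopifnot(inherits(x, "mixed_data"))
  if (length(rules) && is.null(names(rules))) {
    names(rules) <- paste0("rule_", seq_along(rules))
  }
  current <- x$data
  removed <- integer(0)
  for (nm in names(rules)) {
    flag <- rules[[nm]](current)
    stopifnot(is.logical(flag), length(flag) == nrow(current))
    flag[is.na(flag)] <- FALSE
    removed[nm] <- sum(flag)
    current <- current[!flag, , drop = FALSE]
    message(sprintf("exclusion rule '%s' removed %d row(s); %d remain",
                    nm, removed[nm], nrow(current)))
  }
  remaining <- nrow(current)
  if (!is.null(select_first)) {
    select_first <- as.integer(select_first)
    if (select_first > remaining) {
      stop(sprintf("select_first (%d) exceeds remaining rows (%d)",
                   select_first, remaining))
    }
    current <- current[seq_len(select_first), , drop = FALSE]
    selected <- select_first
  } else {
    selected <- remaining
  }
  report <- structure(
    list(initial_count = x$n,
         per_rule_removed = removed,
         remaining = remaining,
         selected = selected),
    class = "exclusion_report"
  )
  list(data = mixed_data(current, x$spec), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> initial %d", x$initial_count))
  for (nm in names(x$per_rule_removed)) {
    cat(sprintf(" -> -%d (%s)", x$per_rule_removed[[nm]], nm))
  }
  cat(sprintf(" -> remaining %d, selected %d\n", x$remaining, x$selected))
  invisible(x)
}

#' @export
tidy.exclusion_report <- function(x, ...) {
  tibble::tibble(
    rule = c("initial", names(x$per_rule_removed), "remaining", "selected"),
    count = c(x$initial_count,
              -unname(x$per_rule_removed),
              x$remaining, x$selected)
  )
}

#' Merge sparse categorical levels
#'
#' Either recodes levels with an explicit mapping (e.g. collapsing 13 disease
#' categories into 8 by substantive judgment) or pools every level observed
#' fewer than `min_count` times into a single `"other"` level. The variable
#' specification is updated accordingly.
#'
#' @param x A [mixed_data()].
#' @param variable Name of a categorical variable.
#' @param mapping Named character vector `old level -> merged level`. Levels
#'   not named are kept unchanged.
#' @param min_count Integer; used only when `mapping` is `NULL`.
#' @param other_label Label of the pooled level under `min_count`.
#'
#' @return A new `mixed_data` with the recoded variable.
#' @export
merge_sparse_categories <- function(x, variable, mapping = NULL,
                                    min_count = NULL, other_label = "other") {
  stopifnot(inherits(x, "mixed_data"))
  i <- match(variable, x$spec$name)
  if (is.na(i)) stop("unknown variable: ", variable)
  if (x$spec$domain[i] != "categorical") {
    stop(sprintf("variable '%s' is not categorical", variable))
  }
  old_levels <- x$spec$levels[[i]]
  col <- as.character(x$data[[variable]])
  if (!is.null(mapping)) {
    unknown <- setdiff(names(mapping), old_levels)
    if (length(unknown)) {
      stop("mapping references unknown level(s): ", paste(unknown, collapse = ", "))
    }
    full <- stats::setNames(old_levels, old_levels)
    full[names(mapping)] <- mapping
  } else {
    if (is.null(min_count)) stop("supply either 'mapping' or 'min_count'")
    counts <- table(factor(col, levels = old_levels))
    pooled <- names(counts)[counts < min_count]
    full <- stats::setNames(old_levels, old_levels)
    full[pooled] <- other_label
  }
  new_col <- unname(full[col])
  new_levels <- unique(unname(full[old_levels]))
  values <- x$data
  values[[variable]] <- new_col
  spec <- x$spec
  spec$levels[[i]] <- new_levels
  mixed_data(values, spec)
}

#' Standardize the continuous columns of a mixed dataset
#'
#' Centers and scales every continuous column to sample mean 0 and sample
#' SD 1 (denominator n - 1); categorical columns are untouched. The original
#' means and SDs are retained in the `"standardization"` attribute so reports
#' can map coefficients back to the raw scale. Edge weights of the mixed
#' graphical model are only comparable across variable pairs after this step.
#'
#' @param x A [mixed_data()].
#'
#' @return A standardized `mixed_data` with a `"standardization"` attribute
#'   (tibble of `name`, `mean`, `sd`).
#' @export
standardize_continuous <- function(x) {
  stopifnot(inherits(x, "mixed_data"))
  values <- x$data
  cont <- continuous_vars(x)
  params <- tibble::tibble(name = cont,
                           mean = NA_real_, sd = NA_real_)
  for (j in seq_along(cont)) {
    nm <- cont[j]
    m <- mean(values[[nm]])
    s <- stats::sd(values[[nm]])
    if (!is.finite(s) || s == 0) {
      stop(sprintf("continuous column '%s' has zero variance", nm))
    }
    values[[nm]] <- (values[[nm]] - m) / s
    params$mean[j] <- m
    params$sd[j] <- s
  }
  out <- mixed_data(values, x$spec)
  attr(out, "standardization") <- params
  out
}
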