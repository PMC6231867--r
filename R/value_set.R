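#' Load an EQ-5D-3L value set
#'
#' A value set (tariff) maps each of the 243 EQ-5D-3L health states to a
#' utility anchored at 1 (full health, state 11111) and 0 (death); states
#' worse than death score negative. Scoring is additive: utility =
#' 1 − constant (if any dimension above level 1) − per-dimension level
#' decrements − an extra term if any dimension is at level 3.
#'
#' Two sets are bundled: `"dutch_tariff_3l"`, the Dutch time trade-off
#' tariff (Lamers et al. 2006, minimum −0.329), and `"toy_linear"`, a small
#' hand-checkable set for testing. A custom set can be supplied as a YAML
#' file with the same fields.
#'
#' @param name Name of a bundled value set, ignored when `file` is given.
#' @param file Path to a value-set YAML file.
#' @return An object of class `eq5d3l_value_set`: a list with the tariff
#'   coefficients, the declared `minimum`, and the set `name`.
#' @examples
#' vs <- eq5d3l_value_set("dutch_tariff_3l")
#' score_eq5d3l(c(1, 1, 1, 1, 1), vs)   # full health -> 1
#' score_eq5d3l(c(3, 3, 3, 3, 3), vs)   # worst state -> -0.329
#' @export
eq5d3l_value_set <- function(name = "dutch_tariff_3l", file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "value_sets", paste0(name, ".yaml"),
                        package = "trialcua")
    if (!nzchar(file)) {
      stop("unknown bundled value set: '", name, "'", call. = FALSE)
    }
  }
  spec <- yaml::read_yaml(file)
  dec <- vapply(
    eq5d_dimensions,
    function(d) c(spec$decrements[[d]]$level2, spec$decrements[[d]]$level3),
    numeric(2)
  )
  vs <- structure(
    list(
      name = spec$name,
      constant_any_problem = spec$constant_any_problem,
      any_level3 = spec$any_level3,
      decrements = t(dec),  # 5 dimensions x levels 2:3
      minimum = spec$minimum
    ),
    class = "eq5d3l_value_set"
  )
  validate_value_set(vs)
  vs
}

validate_value_set <- function(vs) {
  u <- eq5d3l_profiles(vs)$utility
  if (abs(max(u) - 1) > 1e-12) {
    stop("value set '", vs$name, "' does not score full health (11111) as 1",
         call. = FALSE)
  }
  if (abs(min(u) - vs$minimum) > 1e-9) {
    stop("value set '", vs$name, "': minimum over the 243 states (",
         min(u), ") does not equal the declared minimum (", vs$minimum, ")",
         call. = FALSE)
  }
  invisible(vs)
}

#' @export
print.eq5d3l_value_set <- function(x, ...) {
  cat("EQ-5D-3L value set '", x$name, "' (range ", x$minimum, " to 1)\n",
      sep = "")
  invisible(x)
}

#' Score EQ-5D-3L profiles
#'
#' Converts EQ-5D-3L dimension levels into utilities under a value set.
#'
#' @param profile A length-5 vector of levels in `{1, 2, 3}` (order:
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression), an `n x 5` matrix, or a data frame containing the
#'   five dimension columns. Rows with any missing level score `NA`.
#' @param value_set An [eq5d3l_value_set()].
#' @return Numeric vector of utilities in `[minimum, 1]`.
#' @export
score_eq5d3l <- function(profile, value_set) {
  stopifnot(inherits(value_set, "eq5d3l_value_set"))
  L <- as_profile_matrix(profile)
  bad <- !is.na(L) & !(L %in% c(1, 2, 3))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid EQ-5D-3L level ", L[bad][1], " in dimension '",
         eq5d_dimensions[idx[2]], "' (levels must be 1, 2 or 3)",
         call. = FALSE)
  }
  dec2 <- value_set$decrements[, 1]
  dec3 <- value_set$decrements[, 2]
  loss <- (L == 2) %*% dec2 + (L == 3) %*% dec3
  any_prob <- apply(L > 1, 1, any)
  any3 <- apply(L == 3, 1, any)
  u <- 1 - loss[, 1] -
    value_set$constant_any_problem * any_prob -
    value_set$any_level3 * any3
  u[apply(is.na(L), 1, any)] <- NA_real_
  as.numeric(u)
}

as_profile_matrix <- function(profile) {
  if (is.data.frame(profile)) {
    missing_cols <- setdiff(eq5d_dimensions, names(profile))
    if (length(missing_cols)) {
      stop("profile data frame lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    L <- as.matrix(profile[eq5d_dimensions])
  } else if (is.matrix(profile)) {
    if (ncol(profile) != 5) stop("profile matrix must have 5 columns", call. = FALSE)
    L <- profile
  } else {
    if (length(profile) != 5) stop("a profile is 5 levels", call. = FALSE)
    L <- matrix(profile, nrow = 1)
  }
  storage.mode(L) <- "double"
  colnames(L) <- eq5d_dimensions
  L
}

#' Enumerate all 243 EQ-5D-3L states with their utilities
#'
#' @param value_set An [eq5d3l_value_set()].
#' @return A tibble with the five dimension columns and `utility`, in
#'   lexicographic state order.
#' @export
eq5d3l_profiles <- function(value_set) {
  grid <- expand.grid(
    anxiety_depression = 1:3, pain_discomfort = 1:3,
    usual_activities = 1:3, self_care = 1:3, mobility = 1:3
  )[, 5:1]
  grid <- tibble::as_tibble(grid)
  grid$utility <- score_eq5d3l(grid, value_set)
  grid
}

# Sorted unique achievable utilities and one representative profile per
# value (first in enumeration order); used to snap latent utilities.
utility_grid <- function(value_set) {
  prof <- eq5d3l_profiles(value_set)
  ord <- order(prof$utility)
  prof <- prof[ord, ]
  keep <- !duplicated(prof$utility)
  list(
    utilities = prof$utility[keep],
    profiles = as.matrix(prof[keep, eq5d_dimensions])
  )
}
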