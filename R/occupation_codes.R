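#' Hierarchical occupation codes
#'
#' Occupation codes follow a five-level hierarchical digit structure
#' (DISCO-08 / ISCO-08 style): levels 1--4 are 1-, 2-, 3- and 4-digit
#' codes, level 5 is a 6-digit code. A code's parent is its digit prefix
#' at the next coarser level, so the code set forms a forest rooted at
#' the 1-digit major groups.
#'
#' Codes are carried as plain character strings; [parse_code()] validates
#' them and [code_level()] / [code_parent()] expose the hierarchy.
#'
#' @name occupation-codes
NULL

# digit lengths per hierarchy level; length 5 is not a valid code
.code_lengths <- c(1L, 2L, 3L, 4L, 6L)

#' Validate occupation codes
#'
#' Checks that each element is a non-empty digit string of length 1, 2,
#' 3, 4 or 6 and returns it unchanged. Anything else (including 5-digit
#' strings) is an error naming the offending value.
#'
#' @param raw character vector of candidate codes.
#' @return `raw`, validated, as character.
#' @examples
#' parse_code("5131")          # level 4, parent "513"
#' code_level("226610")        # 5
#' @export
parse_code <- function(raw) {
  raw <- as.character(raw)
  if (length(raw) == 0L) stop("no codes supplied")
  bad <- !grepl("^[0-9]+$", raw) | !(nchar(raw) %in% .code_lengths)
  if (any(bad)) {
    stop("invalid occupation code(s): ",
         paste(sQuote(unique(raw[bad])), collapse = ", "),
         " (codes must be digit strings of length 1, 2, 3, 4 or 6)")
  }
  raw
}

#' @rdname parse_code
#' @param code validated code(s).
#' @return `code_level()`: integer level 1--5.
#' @export
code_level <- function(code) {
  code <- parse_code(code)
  match(nchar(code), .code_lengths)
}

#' @rdname parse_code
#' @return `code_parent()`: the prefix at the next coarser level, or
#'   `NA` for level-1 codes.
#' @export
code_parent <- function(code) {
  lev <- code_level(code)
  out <- ifelse(lev > 1L, substr(code, 1L, .code_lengths[pmax(lev - 1L, 1L)]), NA_character_)
  out
}

#' Codes below a given code
#'
#' Returns the members of `universe` that have `code` as a proper digit
#' prefix (i.e. all codes filed under it in the hierarchy).
#'
#' @param code a single validated code.
#' @param universe character vector of codes to scan.
#' @return character vector (possibly empty), in `universe` order.
#' @export
descendants <- function(code, universe) {
  code <- parse_code(code)
  stopifnot(length(code) == 1L)
  universe <- parse_code(universe)
  universe[startsWith(universe, code) & nchar(universe) > nchar(code)]
}

#' Impute expert ratings across the code hierarchy
#'
#' Expert ratings are given per occupational group; `grouping` maps
#' groups to member codes (a group id that never appears in `grouping`
#' is taken to be the code itself). Codes in `universe` that carry no
#' rating receive, per rater and exposure, the arithmetic mean of that
#' same rater's values over the nearest rated codes below them (the
#' minimal-level rated descendants); codes with no rated descendant fall
#' back to the nearest ancestor that can be resolved the same way.
#' Imputation never pools across raters, and category 0 ("cannot be
#' assessed") is treated as missing for that rater.
#'
#' @param ratings data.frame with columns `group_id`, `rater_id`,
#'   `exposure`, `category`.
#' @param universe character vector of codes that must end up rated.
#' @param grouping optional data.frame with columns `group_id`, `code`.
#' @return data.frame `code`, `rater_id`, `exposure`, `category` covering
#'   every (code in universe) x rater x exposure combination; imputed
#'   values may be fractional.
#' @export
impute_ratings <- function(ratings, universe, grouping = NULL) {
  stopifnot(all(c("group_id", "rater_id", "exposure", "category") %in% names(ratings)))
  universe <- parse_code(universe)

  # expand group-level ratings to member codes
  if (!is.null(grouping) && nrow(grouping)) {
    grouping$code <- parse_code(grouping$code)
    exp_r <- merge(ratings, grouping, by = "group_id")
    ungrouped <- !(ratings$group_id %in% grouping$group_id)
    if (any(ungrouped)) {
      self_r <- ratings[ungrouped, ]
      self_r$code <- parse_code(self_r$group_id)
      exp_r <- rbind(exp_r[, c("code", "rater_id", "exposure", "category")],
                     self_r[, c("code", "rater_id", "exposure", "category")])
    } else {
      exp_r <- exp_r[, c("code", "rater_id", "exposure", "category")]
    }
  } else {
    exp_r <- ratings
    exp_r$code <- parse_code(exp_r$group_id)
    exp_r <- exp_r[, c("code", "rater_id", "exposure", "category")]
  }
  # 0 = cannot be assessed -> missing for that rater
  exp_r$category[exp_r$category == 0] <- NA_real_

  raters <- sort(unique(exp_r$rater_id))
  exposures <- sort(unique(exp_r$exposure))
  out <- vector("list", length(raters) * length(exposures))
  k <- 0L
  unresolved <- character(0)
  for (r in raters) {
    for (e in exposures) {
      sl <- exp_r[exp_r$rater_id == r & exp_r$exposure == e & !is.na(exp_r$category), ]
      vals <- tapply(sl$category, sl$code, mean)  # a code rated via >1 group: average
      filled <- .impute_one(universe, vals)
      unresolved <- union(unresolved, filled$unresolved)
      k <- k + 1L
      out[[k]] <- data.frame(code = universe, rater_id = r, exposure = e,
                             category = filled$value, stringsAsFactors = FALSE)
    }
  }
  if (length(unresolved)) {
    stop("unresolvable code(s): no rating, rated descendant or rated ancestor for ",
         paste(sQuote(sort(unresolved)), collapse = ", "))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$code, res$rater_id, res$exposure), ]
  rownames(res) <- NULL
  res
}

# Impute one rater x exposure slice. `vals` is a named vector of rated
# categories keyed by code. Returns values for `universe` plus the codes
# that could not be resolved.
.impute_one <- function(universe, vals) {
  rated_codes <- names(vals)
  resolve_below <- function(code) {
    desc <- rated_codes[startsWith(rated_codes, code) & nchar(rated_codes) > nchar(code)]
    if (!length(desc)) return(NA_real_)
    minlen <- min(nchar(desc))          # minimal-level descendants only
    mean(vals[desc[nchar(desc) == minlen]])
  }
  resolve <- function(code) {
    if (code %in% rated_codes) return(unname(vals[code]))
    v <- resolve_below(code)
    if (!is.na(v)) return(v)
    # ancestor fallback: nearest prefix that is rated or has rated descendants
    lev <- code_level(code)
    while (lev > 1L) {
      lev <- lev - 1L
      anc <- substr(code, 1L, .code_lengths[lev])
      if (anc %in% rated_codes) return(unname(vals[anc]))
      v <- resolve_below(anc)
      if (!is.na(v)) return(v)
    }
    NA_real_
  }
  value <- vapply(universe, resolve, numeric(1))
  list(value = unname(value), unresolved = universe[is.na(value)])
}
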