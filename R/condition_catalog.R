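#' Chronic-condition catalogs
#'
#' A condition catalog defines the chronic conditions the segmenter can
#' detect: for each condition a set of ICD-9 and ICD-10 code prefixes, a set
#' of verbatim primary-care condition labels, and a class (`stable`,
#' `complex` or `terminal`) that drives segment assignment.  Conditions in
#' the `complex` class define the complex-chronic segments; conditions in the
#' `terminal` class trigger the end-of-life segment.
#'
#' The catalog is represented as a tibble with one row per condition and
#' list-columns `icd9`, `icd10` and `primary_care` holding the patterns.
#'
#' @name condition_catalog
NULL

catalog_categories <- function() c("stable", "complex", "terminal")
catalog_systems <- function() c("icd9", "icd10", "primary_care")

new_condition_catalog <- function(conditions, version = "unversioned") {
  structure(conditions, version = version,
            class = c("condition_catalog", class(tibble::tibble())))
}

#' Load a condition catalog from a JSON file
#'
#' The file holds a `version` string and a `conditions` array; each entry has
#' keys `name`, `category` (`stable`/`complex`/`terminal`), `source`, and
#' pattern lists `icd9`, `icd10`, `primary_care`.  Every condition must carry
#' at least one pattern or label; names must be unique; within a code system
#' no two conditions may share an identical pattern.
#'
#' @param path Path to a catalog JSON file.
#' @return A `condition_catalog` tibble.
#' @seealso [default_catalog()], [match_code()]
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("catalog file not found: %s", path))
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    abort(sprintf("catalog file %s is not valid JSON: %s",
                                  path, conditionMessage(e)))
                  })
  entries <- raw$conditions
  if (is.null(entries) || length(entries) == 0) {
    abort(sprintf("catalog file %s has an empty or missing 'conditions' list", path))
  }
  norm_patterns <- function(x) normalize_code(unlist(x) %||% character())
  rows <- purrr::imap(entries, function(e, i) {
    label <- e$name %||% sprintf("entry %d", i)
    if (is.null(e$name) || !nzchar(e$name)) {
      abort(sprintf("catalog entry %d has no name", i))
    }
    if (is.null(e$category) || !(e$category %in% catalog_categories())) {
      abort(sprintf("condition '%s': category must be one of %s", label,
                    paste(catalog_categories(), collapse = "/")))
    }
    icd9 <- norm_patterns(e$icd9)
    icd10 <- norm_patterns(e$icd10)
    pc <- tolower(trimws(unlist(e$primary_care) %||% character()))
    if (length(icd9) + length(icd10) + length(pc) == 0) {
      abort(sprintf("condition '%s' has no code patterns or labels", label))
    }
    tibble::tibble(name = e$name, category = e$category,
                   source = e$source %||% "custom",
                   icd9 = list(icd9), icd10 = list(icd10),
                   primary_care = list(pc))
  })
  conditions <- dplyr::bind_rows(rows)
  dup <- conditions$name[duplicated(conditions$name)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate condition name(s) in catalog: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  for (sys in catalog_systems()) {
    pat <- unlist(conditions[[sys]])
    dup <- unique(pat[duplicated(pat)])
    if (length(dup) > 0) {
      abort(sprintf("pattern(s) shared by two conditions in system %s: %s",
                    sys, paste(dup, collapse = ", ")))
    }
  }
  new_condition_catalog(conditions, version = raw$version %||% "unversioned")
}

#' The built-in 34-condition catalog
#'
#' Returns the catalog shipped with the package: the chronic-disease roster
#' used by the six-segment framework (the Singapore CDMP core diseases
#' extended with Charlson/Elixhauser comorbidities), with ICD-9/ICD-10
#' prefixes adapted from the published Quan et al. administrative-code
#' mappings.  Five conditions are complex-defining (diabetes with chronic
#' complications, non-metastatic malignancy, atrial fibrillation,
#' moderate/severe liver disease, thromboembolism) and metastatic disease is
#' terminal; all remaining conditions are stable.  Every category can be
#' overridden by editing a copy of the shipped JSON file and loading it with
#' [load_catalog()].
#'
#' @return A `condition_catalog` tibble with 34 rows.
#' @examples
#' cat34 <- default_catalog()
#' nrow(cat34)
#' match_code("I10", "icd10", cat34)
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "condition_catalog.json",
                      package = "popsegment", mustWork = TRUE)
  load_catalog(path)
}

#' Normalize a diagnosis code
#'
#' Uppercases, strips periods and surrounding whitespace.  ICD exports differ
#' in dotted vs undotted forms ("i10.9" vs "I109"); normalization makes
#' prefix matching insensitive to the dialect.
#'
#' @param code Character vector of raw codes.
#' @return Character vector of normalized codes.
#' @export
normalize_code <- function(code) {
  toupper(gsub(".", "", trimws(code), fixed = TRUE))
}

#' Map a raw diagnosis code to conditions
#'
#' For ICD systems a condition matches when any of its patterns is a prefix
#' of the normalized code; for primary-care codes the (case-folded) label
#' must match exactly.  A code can in principle map to several conditions;
#' the shipped catalog keeps pattern sets disjoint so each code maps to at
#' most one.
#'
#' @param code A single raw code string.
#' @param system One of `"icd9"`, `"icd10"`, `"primary_care"`
#'   (case-insensitive; `"ICD9"`/`"ICD10"` accepted).
#' @param catalog A `condition_catalog`.
#' @return Character vector of matching condition names (possibly empty).
#' @examples
#' match_code("i10.9", "icd10", default_catalog())
#' @export
match_code <- function(code, system, catalog) {
  stopifnot(length(code) == 1, length(system) == 1)
  system <- normalize_system(system)
  code <- if (system == "primary_care") tolower(trimws(code)) else normalize_code(code)
  if (!nzchar(code)) abort("code is empty after normalization")
  hits <- purrr::map_lgl(catalog[[system]], function(patterns) {
    if (length(patterns) == 0) return(FALSE)
    if (system == "primary_care") any(patterns == code)
    else any(startsWith(code, patterns))
  })
  catalog$name[hits]
}

normalize_system <- function(system) {
  s <- tolower(trimws(system))
  if (!s %in% catalog_systems()) {
    abort(sprintf("unknown code system '%s' (expected icd9, icd10 or primary_care)",
                  system))
  }
  s
}

# Vectorized matcher used by the segmentation engine: takes parallel vectors
# of codes and systems, returns a tibble (idx, condition) with one row per
# (input row, matched condition).  Matching is done once per unique
# (system, code) pair, so cost scales with code diversity, not cohort size.
match_codes_bulk <- function(codes, systems, catalog) {
  stopifnot(length(codes) == length(systems))
  systems <- tolower(trimws(systems))
  norm <- ifelse(systems == "primary_care",
                 tolower(trimws(codes)), normalize_code(codes))
  uniq <- dplyr::distinct(tibble::tibble(system = systems, code = norm))
  pat_tbl <- dplyr::bind_rows(purrr::map(catalog_systems(), function(sys) {
    tibble::tibble(system = sys, condition = rep(catalog$name,
                                                 lengths(catalog[[sys]])),
                   pattern = unlist(catalog[[sys]]) %||% character())
  }))
  hits <- purrr::map_dfr(split(uniq, uniq$system), function(u) {
    sys <- u$system[1]
    pats <- pat_tbl[pat_tbl$system == sys, ]
    if (nrow(pats) == 0) return(tibble::tibble())
    if (sys == "primary_care") {
      m <- dplyr::inner_join(u, pats, by = c("system", "code" = "pattern"))
      return(tibble::tibble(system = m$system, code = m$code,
                            condition = m$condition))
    }
    # prefix join: for each pattern length present, join on the code truncated
    # to that length
    purrr::map_dfr(unique(nchar(pats$pattern)), function(L) {
      p <- pats[nchar(pats$pattern) == L, ]
      key <- substr(u$code, 1, L)
      idx <- match(key, p$pattern)
      ok <- !is.na(idx) & nchar(u$code) >= L
      tibble::tibble(system = u$system[ok], code = u$code[ok],
                     condition = p$condition[idx[ok]])
    })
  })
  input <- tibble::tibble(idx = seq_along(norm), system = systems, code = norm)
  out <- dplyr::inner_join(input, hits, by = c("system", "code"),
                           relationship = "many-to-many")
  tibble::tibble(idx = out$idx, condition = out$condition)
}

#' @export
print.condition_catalog <- function(x, ...) {
  cat(sprintf("<condition_catalog> %d conditions (%s)\n",
              nrow(x), attr(x, "version")))
  cat(sprintf("  stable: %d, complex: %d, terminal: %d\n",
              sum(x$category == "stable"), sum(x$category == "complex"),
              sum(x$category == "terminal")))
  NextMethod()
}
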