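# Synthetic terminology tables and an independent brute-force oracle.  The
# generator emulates the two catalog shapes the compiler targets: a
# header-bearing CODE/DISPLAY/INACTIVE/PARENT CSV, and a headerless
# pipe-separated index-catalog layout (validity flag, stable code, several
# mapped-code columns, free text) like national diagnosis index files.

.fixture_words <- c(
  "acute", "chronic", "benign", "malignant", "primary", "secondary",
  "lesion", "syndrome", "disorder", "disease", "deficiency", "anomaly",
  "stenosis", "fibrosis", "necrosis", "atrophy", "hyperplasia", "carcinoma",
  "fracture", "infection", "inflammation", "neuropathy", "myopathy",
  "dysplasia", "embolism", "thrombosis", "sclerosis", "ischemia", "edema",
  "rupture", "occlusion", "prolapse", "hernia", "ulcer", "cyst", "polyp",
  "abscess", "granuloma", "hematoma", "palsy")

#' Describe a synthetic table fixture
#'
#' The generator is fully deterministic: the same spec and seed produce a
#' byte-identical file.  Planted defects make the fixture trip exactly one
#' documented validation finding each, at a predictable line.
#'
#' @param rows number of data rows.
#' @param seed RNG seed.
#' @param layout `"hierarchy_csv"` (header CODE,DISPLAY,INACTIVE,PARENT) or
#'   `"alpha_like"` (headerless 7-column pipe file:
#'   validity|code|primary-code|secondary-code|extra-code|orpha|text).
#' @param inactive_fraction fraction of rows flagged inactive.
#' @param max_depth maximum hierarchy depth (hierarchy_csv only).
#' @param parent_fraction fraction of non-root rows linked to a parent.
#' @param duplicate_code_fraction fraction of rows that repeat an earlier
#'   code (merged by the compiler; adds a second parent link).
#' @param defects character subset of `duplicate_display_conflict`,
#'   `dangling_parent`, `cycle`, `ragged_row`.
#' @return a validated `fixture_spec` list.
#' @export
fixture_spec <- function(rows, seed = 1L,
                         layout = c("hierarchy_csv", "alpha_like"),
                         inactive_fraction = 0.15, max_depth = 3L,
                         parent_fraction = 0.7,
                         duplicate_code_fraction = 0,
                         defects = character()) {
  layout <- match.arg(layout)
  stopifnot(rows >= 1L, seed == as.integer(seed),
            inactive_fraction >= 0, inactive_fraction <= 1,
            duplicate_code_fraction >= 0, duplicate_code_fraction < 1,
            all(defects %in% c("duplicate_display_conflict", "dangling_parent",
                               "cycle", "ragged_row")))
  structure(list(rows = as.integer(rows), seed = as.integer(seed),
                 layout = layout, inactive_fraction = inactive_fraction,
                 max_depth = as.integer(max_depth),
                 parent_fraction = parent_fraction,
                 duplicate_code_fraction = duplicate_code_fraction,
                 defects = defects),
            class = "fixture_spec")
}

with_fixture_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

random_display <- function(n_words) {
  w <- sample(.fixture_words, n_words, replace = TRUE)
  w[[1L]] <- paste0(toupper(substr(w[[1L]], 1L, 1L)), substr(w[[1L]], 2L, 99L))
  paste(w, collapse = " ")
}

#' Generate a synthetic terminology table
#'
#' Writes the table (LF line endings) and returns a manifest that tests use
#' as ground truth: row count, distinct codes, expected concept and
#' property counts, and each planted defect with its 1-based line number.
#'
#' @param spec a [fixture_spec()].
#' @param path output file path.
#' @return the manifest (a list), invisibly the same list.
#' @export
generate_table <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    if (spec$layout == "hierarchy_csv") {
      generate_hierarchy_csv(spec, path)
    } else {
      generate_alpha_like(spec, path)
    }
  })
}

generate_hierarchy_csv <- function(spec, path) {
  n <- spec$rows
  n_dup <- floor(n * spec$duplicate_code_fraction)
  n_base <- n - n_dup
  codes <- sprintf("C%04d", seq_len(n_base))
  displays <- vapply(seq_len(n_base),
                     function(i) random_display(sample(2:3, 1L)),
                     character(1))
  inactive <- ifelse(stats::runif(n_base) < spec$inactive_fraction,
                     "YES", "NO")
  depth <- rep(1L, n_base)
  parents <- character(n_base)
  for (i in seq_len(n_base)[-1L]) {
    eligible <- which(depth[seq_len(i - 1L)] < spec$max_depth)
    if (length(eligible) && stats::runif(1L) < spec$parent_fraction) {
      p <- eligible[[sample.int(length(eligible), 1L)]]
      parents[[i]] <- codes[[p]]
      depth[[i]] <- depth[[p]] + 1L
    }
  }

  rows <- data.frame(code = codes, display = displays, inactive = inactive,
                     parent = parents, stringsAsFactors = FALSE)
  if (n_dup > 0L) {
    # duplicated rows repeat the code and display of a base row and attach
    # one extra parent (merged into a poly-hierarchy concept); the extra
    # parent must not be the row's own code or one of its descendants,
    # which would plant an unintended hierarchy cycle
    parent_adj <- lapply(seq_len(n_base), function(i) {
      if (nzchar(parents[[i]])) match(parents[[i]], codes) else integer()
    })
    reachable <- function(from, to) {
      # is `to` an ancestor of `from` under the current (multi-)parent edges?
      seen <- integer()
      frontier <- from
      while (length(frontier)) {
        if (to %in% frontier) {
          return(TRUE)
        }
        seen <- c(seen, frontier)
        frontier <- setdiff(unique(unlist(parent_adj[frontier])), seen)
      }
      FALSE
    }
    src <- sample.int(n_base, n_dup, replace = TRUE)
    extra_parent <- vapply(src, function(s) {
      safe <- which(vapply(seq_len(n_base),
                           function(p) p != s && !reachable(p, s),
                           logical(1)))
      if (length(safe) == 0L) {
        return("")
      }
      p <- safe[[sample.int(length(safe), 1L)]]
      parent_adj[[s]] <<- c(parent_adj[[s]], p)
      codes[[p]]
    }, character(1))
    rows <- rbind(rows, data.frame(
      code = codes[src], display = displays[src], inactive = "",
      parent = extra_parent, stringsAsFactors = FALSE))
  }

  defects <- list()
  if ("dangling_parent" %in% defects_of(spec, "dangling_parent")) {
    i <- pick_row(nrow(rows))
    rows$parent[[i]] <- "MISSING"
    defects$dangling_parent <- list(type = "dangling_parent",
                                    line = i + 1L, code = rows$code[[i]])
  }
  if ("cycle" %in% spec$defects) {
    child <- which(nzchar(rows$parent) & rows$parent != "MISSING")[[1L]]
    p <- match(rows$parent[[child]], rows$code)
    rows$parent[[p]] <- rows$code[[child]]
    defects$cycle <- list(type = "cycle", line = p + 1L,
                          codes = sort(c(rows$code[[child]], rows$code[[p]])))
  }
  if ("duplicate_display_conflict" %in% spec$defects) {
    i <- pick_row(nrow(rows))
    rows <- rbind(rows, data.frame(code = rows$code[[i]],
                                   display = "CONFLICTING DISPLAY",
                                   inactive = "", parent = "",
                                   stringsAsFactors = FALSE))
    defects$duplicate_display_conflict <- list(
      type = "duplicate_display_conflict", line = nrow(rows) + 1L,
      code = rows$code[[i]])
  }

  lines <- c("CODE,DISPLAY,INACTIVE,PARENT",
             sprintf("%s,%s,%s,%s", rows$code, rows$display, rows$inactive,
                     rows$parent))
  if ("ragged_row" %in% spec$defects) {
    i <- pick_row(nrow(rows))
    lines[[i + 1L]] <- sub(",[^,]*$", "", lines[[i + 1L]])
    defects$ragged_row <- list(type = "ragged_row", line = i + 1L)
  }
  write_lf(lines, path)

  manifest <- list(
    layout = "hierarchy_csv", path = path, seed = spec$seed,
    data_rows = length(lines) - 1L,
    distinct_codes = length(unique(rows$code)),
    expected_concepts = length(unique(rows$code)),
    expected_parent_properties = sum(nzchar(rows$parent)),
    expected_inactive_properties = sum(rows$inactive == "YES"),
    defects = unname(defects))
  invisible(manifest)
}

defects_of <- function(spec, what) spec$defects[spec$defects == what]

pick_row <- function(n) max(2L, min(n, as.integer(n %/% 2L)))

generate_alpha_like <- function(spec, path) {
  n <- spec$rows
  validity <- ifelse(stats::runif(n) < spec$inactive_fraction, "0", "1")
  codes <- as.character(seq_len(n) + 100000L)
  icd <- sprintf("%s%02d.%d", sample(LETTERS, n, replace = TRUE),
                 sample.int(99, n, replace = TRUE) - 1L,
                 sample.int(10, n, replace = TRUE) - 1L)
  icd2 <- ifelse(stats::runif(n) < 0.3,
                 sprintf("%s%02d.%d", sample(LETTERS, n, replace = TRUE),
                         sample.int(99, n, replace = TRUE) - 1L,
                         sample.int(10, n, replace = TRUE) - 1L),
                 "")
  extra <- ifelse(stats::runif(n) < 0.05,
                  sprintf("%s%02d", sample(LETTERS, n, replace = TRUE),
                          sample.int(99, n, replace = TRUE) - 1L),
                  "")
  orpha <- ifelse(stats::runif(n) < 0.2,
                  as.character(sample.int(999999L, n, replace = TRUE)),
                  "")
  nw <- sample(2:6, n, replace = TRUE)
  text <- vapply(nw, random_display, character(1))

  lines <- sprintf("%s|%s|%s|%s|%s|%s|%s", validity, codes, icd, icd2,
                   extra, orpha, text)
  defects <- list()
  if ("ragged_row" %in% spec$defects) {
    i <- pick_row(n)
    lines[[i]] <- sub("\\|[^|]*$", "", lines[[i]])
    defects$ragged_row <- list(type = "ragged_row", line = i)
  }
  write_lf(lines, path)

  manifest <- list(
    layout = "alpha_like", path = path, seed = spec$seed,
    data_rows = n,
    distinct_codes = n,
    expected_concepts = n,
    expected_inactive_properties = sum(validity == "0"),
    expected_primary_code_properties = n,
    expected_secondary_code_properties = sum(nzchar(icd2)),
    expected_orpha_properties = sum(nzchar(orpha)),
    defects = unname(defects))
  invisible(manifest)
}

write_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"), "\n"))),
           con)
  invisible(path)
}

#' Brute-force CodeSystem oracle
#'
#' Builds the expected CodeSystem JSON directly from the table by plain
#' row-by-row iteration, sharing no code with the compiler beyond the
#' canonical JSON writer.  Intended for equivalence tests on small tables
#' (at most 1,000 rows); deliberately naive.
#'
#' @param path the delimited table.
#' @param mapping a plain list: `delimiter`, `has_header`, and 1-based
#'   column indices `code`, `display`, `inactive`, `parent` (NA to skip),
#'   `true_values` (cell values counted as inactive), `properties` (list of
#'   `list(code, col, type)` applied in order).
#' @param meta a plain named list of resource metadata (`id`, `url`,
#'   `version`, `name`, `title`, `status`, `experimental`, `date`,
#'   `publisher`, `description`, `copyright`, `caseSensitive`, `content`).
#' @param mode `"R4B"` or `"R5"`.
#' @return the canonical JSON text.
#' @export
oracle_codesystem <- function(path, mapping, meta, mode = "R4B") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  stopifnot(length(lines) <= 1001L)
  if (isTRUE(mapping$has_header)) lines <- lines[-1L]

  cell <- function(row, i) if (is.na(i) || i > length(row)) "" else row[[i]]

  # ordered accumulation keyed by code
  order_codes <- character()
  display_of <- list()
  props_of <- list()

  for (ln in lines) {
    row <- strsplit(paste0(ln, mapping$delimiter, "\x01"),
                    mapping$delimiter, fixed = TRUE)[[1L]]
    row <- row[-length(row)]
    code <- cell(row, mapping$code)
    if (!code %in% order_codes) {
      order_codes <- c(order_codes, code)
      display_of[[code]] <- NA_character_
      props_of[[code]] <- list()
    }
    d <- cell(row, mapping$display)
    if (nzchar(d) && is.na(display_of[[code]])) display_of[[code]] <- d
    for (pm in mapping$properties %||% list()) {
      v <- cell(row, pm$col)
      if (!nzchar(v)) next
      el <- switch(pm$type, code = "valueCode", string = "valueString",
                   integer = "valueInteger", boolean = "valueBoolean",
                   dateTime = "valueDateTime", decimal = "valueDecimal")
      val <- switch(pm$type, integer = as.integer(v),
                    boolean = tolower(v) %in% c("true", "yes", "y", "1"),
                    decimal = json_number(v), v)
      p <- list(code = pm$code)
      p[[el]] <- val
      props_of[[code]] <- c(props_of[[code]], list(p))
    }
    iv <- cell(row, mapping$inactive)
    if (nzchar(iv) && toupper(iv) %in% toupper(mapping$true_values %||%
                                               c("YES", "Y", "TRUE", "1"))) {
      props_of[[code]] <- c(props_of[[code]],
                            list(list(code = "inactive",
                                      valueBoolean = TRUE)))
    }
    pv <- cell(row, mapping$parent)
    if (nzchar(pv)) {
      props_of[[code]] <- c(props_of[[code]],
                            list(list(code = "parent", valueCode = pv)))
    }
  }

  # implicit declarations appear in order of first use in the concept
  # stream (document order of the output concepts)
  implicit_set <- c("parent", "child", "inactive", "deprecated",
                    "notSelectable")
  declared_codes <- vapply(meta$property_declarations %||% list(),
                           function(d) d$code, character(1))
  implicit_used <- character()
  for (code in order_codes) {
    for (p in props_of[[code]]) {
      if (p$code %in% implicit_set && !p$code %in% declared_codes &&
          !p$code %in% implicit_used) {
        implicit_used <- c(implicit_used, p$code)
      }
    }
  }

  concepts <- lapply(order_codes, function(code) {
    node <- list(code = code)
    if (!is.na(display_of[[code]])) node$display <- display_of[[code]]
    if (length(props_of[[code]])) {
      node$property <- json_array(props_of[[code]])
    }
    node
  })

  tree <- list(resourceType = "CodeSystem")
  for (f in c("id", "url", "version", "name", "title", "status",
              "experimental", "date", "publisher", "description",
              "copyright")) {
    if (!is.null(meta[[f]])) tree[[f]] <- meta[[f]]
  }
  if (!is.null(meta$caseSensitive)) tree$caseSensitive <- meta$caseSensitive
  tree$content <- meta$content %||% "complete"
  tree$count <- length(order_codes)
  std_type <- c(parent = "code", child = "code", inactive = "boolean",
                deprecated = "boolean", notSelectable = "boolean")
  decls <- c(
    lapply(meta$property_declarations %||% list(), function(d) {
      out <- list(code = d$code)
      if (!is.null(d$uri)) out$uri <- d$uri
      out$type <- d$type
      out
    }),
    lapply(implicit_used, function(code) {
      list(code = code,
           uri = paste0("http://hl7.org/fhir/concept-properties#", code),
           type = std_type[[code]])
    }))
  if (length(decls)) tree$property <- json_array(decls)
  if (length(concepts)) tree$concept <- json_array(concepts)
  write_canonical_json(tree)
}
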