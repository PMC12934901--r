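# Standoff annotation I/O: parsing brat-style .ann files (T/R/A records),
# corpus-level loading, validation, summaries, and a canonical JSON-lines
# interchange format.

new_corpus <- function(mentions, relations) {
  structure(
    list(mentions = as_tibble(mentions), relations = as_tibble(relations)),
    class = "kg_corpus"
  )
}

empty_mentions <- function() {
  tibble(
    doc_id = character(), mention_id = character(), category = character(),
    surface = character(), span_start = integer(), span_end = integer()
  )
}

empty_relations <- function() {
  tibble(
    doc_id = character(), relation_id = character(),
    relation_type = character(), polarity = character(),
    source_mention = character(), target_mention = character()
  )
}

#' Construct an annotated corpus from mention and relation tables
#'
#' @param mentions Tibble with columns doc_id, mention_id, category, surface,
#'   span_start, span_end.
#' @param relations Tibble with columns doc_id, relation_id, relation_type,
#'   polarity, source_mention, target_mention.
#' @param validate Check structural invariants (default TRUE).
#' @param schema Schema used for validation.
#' @return A `kg_corpus` object (list of the two tibbles).
#' @export
kg_corpus <- function(mentions = empty_mentions(),
                      relations = empty_relations(),
                      validate = TRUE, schema = kg_schema()) {
  corpus <- new_corpus(mentions, relations)
  if (validate) validate_corpus(corpus, schema)
  corpus
}

#' @export
print.kg_corpus <- function(x, ...) {
  cat("<kg_corpus>", n_distinct(x$mentions$doc_id), "documents,",
      nrow(x$mentions), "mentions,", nrow(x$relations), "relations\n")
  invisible(x)
}

#' Validate corpus invariants
#'
#' Checks that mention ids are unique within each document, spans are
#' well-formed (0 <= start < end), categories and relation types belong to
#' the schema vocabulary, polarities are one of beneficial/harmful/neutral,
#' every relation endpoint resolves to a mention in the same document, and
#' no relation links a mention to itself.
#'
#' @param corpus A `kg_corpus`.
#' @param schema A `kg_schema`.
#' @return Invisibly TRUE; aborts with a message listing violations.
#' @export
validate_corpus <- function(corpus, schema = kg_schema()) {
  m <- corpus$mentions
  r <- corpus$relations
  problems <- character()
  dup <- m |> count(.data$doc_id, .data$mention_id) |> filter(n > 1)
  if (nrow(dup) > 0) {
    problems <- c(problems, paste0(
      "duplicate mention ids: ",
      paste(paste0(dup$doc_id, ":", dup$mention_id), collapse = ", ")
    ))
  }
  if (nrow(m) > 0) {
    bad_span <- m$span_start < 0 | m$span_end <= m$span_start
    if (any(bad_span)) {
      problems <- c(problems, paste0(sum(bad_span), " malformed spans"))
    }
    bad_cat <- setdiff(unique(m$category), schema$categories)
    if (length(bad_cat) > 0) {
      problems <- c(problems,
                    paste0("unknown categories: ", paste(bad_cat, collapse = ", ")))
    }
  }
  if (nrow(r) > 0) {
    bad_type <- setdiff(unique(r$relation_type), schema$relation_types)
    if (length(bad_type) > 0) {
      problems <- c(problems,
                    paste0("unknown relation types: ",
                           paste(bad_type, collapse = ", ")))
    }
    bad_pol <- setdiff(unique(r$polarity), KG_POLARITIES)
    if (length(bad_pol) > 0) {
      problems <- c(problems,
                    paste0("unknown polarities: ", paste(bad_pol, collapse = ", ")))
    }
    if (any(r$source_mention == r$target_mention)) {
      problems <- c(problems, "relation with identical source and target mention")
    }
    keys <- paste(m$doc_id, m$mention_id)
    dangling <- !(paste(r$doc_id, r$source_mention) %in% keys) |
      !(paste(r$doc_id, r$target_mention) %in% keys)
    if (any(dangling)) {
      problems <- c(problems,
                    paste0(sum(dangling), " relations with dangling endpoints"))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid corpus:\n  ", paste(problems, collapse = "\n  ")))
  }
  invisible(TRUE)
}

split_ann_line <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) {
    strsplit(line, "\t", fixed = TRUE)[[1]]
  } else {
    # tolerate space-delimited variants: ID, middle, free text
    parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    kind <- substr(parts[1], 1, 1)
    if (kind == "T" && length(parts) >= 5) {
      c(parts[1], paste(parts[2:4], collapse = " "),
        paste(parts[-(1:4)], collapse = " "))
    } else if (length(parts) >= 2) {
      c(parts[1], paste(parts[-1], collapse = " "))
    } else {
      parts
    }
  }
}

#' Parse a standoff annotation document
#'
#' Parses brat-style standoff records for one document:
#' * `T` lines (`ID<TAB>Category Start End<TAB>Text`) become entity mentions;
#' * `R` lines (`ID<TAB>Type Arg1:Tx Arg2:Ty`) become relation instances,
#'   with polarity defaulting to the schema's type-level mapping;
#' * `A` lines (`ID<TAB>Polarity Rx value`) override a relation's polarity.
#'
#' Malformed lines always raise a parse error naming the line number.
#' Schema violations (unknown category, relation type or polarity, dangling
#' or self-referential relations) are collected: in strict mode they abort,
#' otherwise the offending records are dropped and reported in the returned
#' object's `issues` attribute.
#'
#' @param lines Character vector of annotation lines.
#' @param doc_id Document identifier (typically a PubMed id).
#' @param schema A `kg_schema`.
#' @param strict Abort on schema violations (default FALSE).
#' @return A single-document `kg_corpus`; attribute `issues` is a tibble
#'   (line, message) of collected violations.
#' @examples
#' sc <- kg_schema()
#' doc <- parse_standoff(c(
#'   "T1\tnutrition 0 13\tdietary fiber",
#'   "T2\tmicrobiome 30 58\tFaecalibacterium prausnitzii",
#'   "R1\tincreases Arg1:T1 Arg2:T2"
#' ), doc_id = "12345", schema = sc)
#' doc$relations$polarity  # "beneficial" via the type default
#' @export
parse_standoff <- function(lines, doc_id, schema = kg_schema(),
                           strict = FALSE) {
  stopifnot(is.character(doc_id), length(doc_id) == 1)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  issues <- list()
  note <- function(i, msg) {
    issues[[length(issues) + 1]] <<- tibble(line = i, message = msg)
  }

  mentions <- list()
  relations <- list()
  attributes <- list()
  for (i in seq_along(lines)) {
    fields <- split_ann_line(lines[[i]])
    id <- fields[1]
    kind <- substr(id, 1, 1)
    if (kind == "T") {
      if (length(fields) < 3) {
        abort(paste0("parse error at line ", i, ": T record needs 3 fields"))
      }
      mid <- strsplit(trimws(fields[2]), "[[:space:]]+")[[1]]
      if (length(mid) != 3 || anyNA(suppressWarnings(as.integer(mid[2:3])))) {
        abort(paste0("parse error at line ", i,
                     ": expected 'Category Start End'"))
      }
      category <- tolower(mid[1])
      mentions[[length(mentions) + 1]] <- tibble(
        doc_id = doc_id, mention_id = id, category = category,
        surface = fields[3],
        span_start = as.integer(mid[2]), span_end = as.integer(mid[3])
      )
    } else if (kind == "R") {
      if (length(fields) < 2) {
        abort(paste0("parse error at line ", i, ": R record needs 2 fields"))
      }
      mid <- strsplit(trimws(fields[2]), "[[:space:]]+")[[1]]
      args <- grep("^Arg[12]:", mid, value = TRUE)
      if (length(mid) < 3 || length(args) != 2) {
        abort(paste0("parse error at line ", i,
                     ": expected 'Type Arg1:Tx Arg2:Ty'"))
      }
      src <- sub("^Arg1:", "", grep("^Arg1:", mid, value = TRUE)[1])
      tgt <- sub("^Arg2:", "", grep("^Arg2:", mid, value = TRUE)[1])
      relations[[length(relations) + 1]] <- tibble(
        doc_id = doc_id, relation_id = id, relation_type = mid[1],
        polarity = NA_character_, source_mention = src, target_mention = tgt,
        .line = i
      )
    } else if (kind == "A") {
      mid <- strsplit(trimws(fields[2]), "[[:space:]]+")[[1]]
      if (length(mid) != 3) {
        abort(paste0("parse error at line ", i,
                     ": expected 'Polarity Rx value'"))
      }
      attributes[[length(attributes) + 1]] <- tibble(
        target = mid[2], value = tolower(mid[3]), .line = i
      )
    } else {
      abort(paste0("parse error at line ", i,
                   ": unknown record kind '", kind, "'"))
    }
  }

  m <- bind_rows(mentions) %0% empty_mentions()
  if (nrow(m) == 0) m <- empty_mentions()
  r <- dplyr::bind_rows(relations)
  if (nrow(r) == 0) {
    r <- empty_relations()
  } else {
    r$polarity <- default_polarity(r$relation_type, schema)
  }
  for (a in attributes) {
    j <- which(r$relation_id == a$target)
    if (length(j) == 0) {
      note(a$.line, paste0("attribute targets unknown relation ", a$target))
    } else if (!a$value %in% KG_POLARITIES) {
      note(a$.line, paste0("unknown polarity value '", a$value, "'"))
    } else {
      r$polarity[j] <- a$value
    }
  }

  # schema checks: collect and drop, or abort in strict mode
  bad_cat <- !(m$category %in% schema$categories)
  for (j in which(bad_cat)) {
    note(NA_integer_, paste0("unknown category '", m$category[j], "' (",
                             m$mention_id[j], ")"))
  }
  if (nrow(m) > 0 && any(m$span_start < 0 | m$span_end <= m$span_start)) {
    abort(paste0("parse error: malformed span in document ", doc_id))
  }
  keep_m <- m[!bad_cat, , drop = FALSE]
  if (nrow(r) > 0) {
    bad <- rep(FALSE, nrow(r))
    for (j in seq_len(nrow(r))) {
      if (!r$relation_type[j] %in% schema$relation_types) {
        note(r$.line[j], paste0("unknown relation type '",
                                r$relation_type[j], "'"))
        bad[j] <- TRUE
      } else if (is.na(r$polarity[j])) {
        note(r$.line[j], paste0("no default polarity for type '",
                                r$relation_type[j], "'"))
        bad[j] <- TRUE
      }
      if (r$source_mention[j] == r$target_mention[j]) {
        note(r$.line[j], "relation source equals target mention")
        bad[j] <- TRUE
      }
      endpoints_ok <- all(c(r$source_mention[j], r$target_mention[j]) %in%
                            keep_m$mention_id)
      if (!endpoints_ok) {
        note(r$.line[j], paste0("dangling endpoint in ", r$relation_id[j]))
        bad[j] <- TRUE
      }
    }
    r <- r[!bad, , drop = FALSE]
  }
  r$.line <- NULL

  issues <- bind_rows(issues) %0% tibble(line = integer(), message = character())
  if (strict && nrow(issues) > 0) {
    abort(paste0("schema violations in document ", doc_id, ":\n  ",
                 paste(issues$message, collapse = "\n  ")))
  }
  out <- new_corpus(keep_m, r)
  attr(out, "issues") <- issues
  out
}

#' Load an annotated corpus from a directory of .ann files
#'
#' Each `*.ann` file holds one document; the document id is the file name
#' without extension unless a two-column manifest TSV (`file`, `doc_id`)
#' is supplied. In non-strict mode files that fail to parse are skipped and
#' reported in the `failures` attribute.
#'
#' @param path Directory containing `*.ann` files.
#' @param schema A `kg_schema`.
#' @param strict Abort on the first malformed file or schema violation.
#' @param manifest Optional path to a TSV mapping file names to doc ids.
#' @return A `kg_corpus` with attributes `n_documents`, `failures` (tibble
#'   file/message) and `issues`.
#' @export
load_corpus <- function(path, schema = kg_schema(), strict = FALSE,
                        manifest = NULL) {
  if (!dir.exists(path)) abort(paste0("corpus directory not found: ", path))
  files <- sort(list.files(path, pattern = "\\.ann$", full.names = TRUE))
  ids <- sub("\\.ann$", "", basename(files))
  if (!is.null(manifest)) {
    map <- readr::read_tsv(manifest, col_types = "cc", comment = "#")
    idx <- match(basename(files), map$file)
    ids <- ifelse(is.na(idx), ids, map$doc_id[idx])
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate doc_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  docs <- list()
  failures <- list()
  issues <- list()
  for (k in seq_along(files)) {
    res <- tryCatch(
      parse_standoff(readLines(files[k], warn = FALSE), doc_id = ids[k],
                     schema = schema, strict = strict),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (strict) abort(paste0(basename(files[k]), ": ", conditionMessage(res)))
      failures[[length(failures) + 1]] <-
        tibble(file = basename(files[k]), message = conditionMessage(res))
    } else {
      docs[[length(docs) + 1]] <- res
      iss <- attr(res, "issues")
      if (nrow(iss) > 0) {
        issues[[length(issues) + 1]] <- mutate(iss, doc_id = ids[k])
      }
    }
  }
  corpus <- new_corpus(
    bind_rows(purrr::map(docs, "mentions")) %0% empty_mentions(),
    bind_rows(purrr::map(docs, "relations")) %0% empty_relations()
  )
  attr(corpus, "n_documents") <- length(docs)
  attr(corpus, "failures") <- bind_rows(failures) %0%
    tibble(file = character(), message = character())
  attr(corpus, "issues") <- bind_rows(issues) %0%
    tibble(line = integer(), message = character(), doc_id = character())
  corpus
}

#' Summarise a corpus: category shares and relation-type counts
#'
#' @param corpus A non-empty `kg_corpus`.
#' @return A list of class `kg_corpus_summary`:
#'   `categories` (category, n, share in percent to 1 decimal),
#'   `relation_types` (relation_type, n), and `totals`
#'   (documents, mentions, relations).
#' @examples
#' m <- tibble::tibble(
#'   doc_id = "d1", mention_id = c("T1", "T2"),
#'   category = c("nutrition", "disease"),
#'   surface = c("fiber", "obesity"), span_start = c(0L, 10L),
#'   span_end = c(5L, 17L)
#' )
#' corpus_summary(kg_corpus(m))$categories
#' @export
corpus_summary <- function(corpus) {
  if (nrow(corpus$mentions) == 0) abort("corpus has no mentions")
  total <- nrow(corpus$mentions)
  categories <- corpus$mentions |>
    count(category = .data$category, name = "n") |>
    mutate(share = round_half_up(.data$n / total * 100, 1)) |>
    arrange(desc(.data$n), .data$category)
  relation_types <- corpus$relations |>
    count(relation_type = .data$relation_type, name = "n") |>
    arrange(desc(.data$n), .data$relation_type)
  structure(
    list(
      categories = categories,
      relation_types = relation_types,
      totals = tibble(
        documents = n_distinct(c(corpus$mentions$doc_id,
                                 corpus$relations$doc_id)),
        mentions = total,
        relations = nrow(corpus$relations)
      )
    ),
    class = "kg_corpus_summary"
  )
}

#' @export
print.kg_corpus_summary <- function(x, ...) {
  cat("<kg_corpus_summary>\n")
  print(x$totals)
  print(x$categories, n = Inf)
  invisible(x)
}

# ---- canonical JSON-lines interchange -------------------------------------

#' Write a corpus as canonical JSON lines
#'
#' One JSON record per mention or relation, discriminated by a `kind` field.
#' The canonical form is deterministic (records sorted by doc, kind, id).
#'
#' @param corpus A `kg_corpus`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  m <- corpus$mentions |> mutate(kind = "mention") |>
    arrange(.data$doc_id, .data$mention_id)
  r <- corpus$relations |> mutate(kind = "relation") |>
    arrange(.data$doc_id, .data$relation_id)
  recs <- c(
    purrr::map_chr(seq_len(nrow(m)), function(i) {
      jsonlite::toJSON(as.list(m[i, ]), auto_unbox = TRUE)
    }),
    purrr::map_chr(seq_len(nrow(r)), function(i) {
      jsonlite::toJSON(as.list(r[i, ]), auto_unbox = TRUE)
    })
  )
  writeLines(recs, path, useBytes = TRUE)
  invisible(path)
}

#' Read a canonical JSON-lines corpus
#'
#' @param path File written by [write_corpus_jsonl()].
#' @param schema Schema used to validate the result.
#' @return A `kg_corpus`.
#' @export
read_corpus_jsonl <- function(path, schema = kg_schema()) {
  lines <- readLines(path, warn = FALSE)
  recs <- purrr::map(lines, jsonlite::fromJSON)
  kinds <- purrr::map_chr(recs, "kind")
  to_tbl <- function(rs) bind_rows(purrr::map(rs, ~ as_tibble(.x[names(.x) != "kind"])))
  m <- to_tbl(recs[kinds == "mention"]) %0% empty_mentions()
  r <- to_tbl(recs[kinds == "relation"]) %0% empty_relations()
  if (nrow(m) > 0) {
    m <- m |> mutate(span_start = as.integer(.data$span_start),
                     span_end = as.integer(.data$span_end))
  }
  kg_corpus(m, r, schema = schema)
}

# ---- standoff serialization (used by the synthetic generator) -------------

#' Serialize one document of a corpus to standoff lines
#'
#' Emits T lines for mentions, R lines for relations, and an A line per
#' relation making the polarity explicit. `parse_standoff()` of the output
#' reproduces the document exactly.
#'
#' @param corpus A `kg_corpus`.
#' @param doc Document id to serialize.
#' @return Character vector of annotation lines.
#' @export
serialize_standoff <- function(corpus, doc) {
  m <- filter(corpus$mentions, .data$doc_id == doc)
  r <- filter(corpus$relations, .data$doc_id == doc)
  t_lines <- purrr::pmap_chr(m, function(mention_id, category, surface,
                                         span_start, span_end, ...) {
    paste0(mention_id, "\t", category, " ", span_start, " ", span_end,
           "\t", surface)
  })
  r_lines <- purrr::pmap_chr(r, function(relation_id, relation_type,
                                         source_mention, target_mention, ...) {
    paste0(relation_id, "\t", relation_type,
           " Arg1:", source_mention, " Arg2:", target_mention)
  })
  a_lines <- if (nrow(r) == 0) character() else
    paste0("A", seq_len(nrow(r)), "\tPolarity ", r$relation_id, " ", r$polarity)
  c(t_lines, r_lines, a_lines)
}

#' Write a corpus as a directory of .ann files
#'
#' @param corpus A `kg_corpus`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_standoff <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(unique(c(corpus$mentions$doc_id, corpus$relations$doc_id)))
  paths <- purrr::map_chr(ids, function(d) {
    p <- file.path(dir, paste0(d, ".ann"))
    writeLines(serialize_standoff(corpus, d), p, useBytes = TRUE)
    p
  })
  invisible(paths)
}
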