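#' @title Readers and writers
#' @description JSON Lines is the canonical rich input format (CSV carries
#'   only the `SAMPLEID,PANEL_NAME,ANNOTATION` triple); gene information
#'   and segregation results arrive as TSV; reports are written as JSON,
#'   TSV summary or plain text.
#' @name io
NULL

.split_annotation <- function(annotation) {
  parts <- strsplit(annotation, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("annotation must be GENE:NM_accession:c-change, got '",
         annotation, "'", call. = FALSE)
  }
  if (!grepl("^NM_[0-9]+(\\.[0-9]+)?$", parts[2])) {
    stop("'", parts[2], "' is not an NM_ transcript accession",
         call. = FALSE)
  }
  list(gene = parts[1], transcript = parts[2], hgvs_c = parts[3])
}

#' Read a gene-information table
#'
#' Tab-separated, with header `symbol, inheritance, missense_z,
#' benign_nonvus_missense, total_nonvus_missense, lof_mechanism,
#' bp1_z_rule`; `inheritance` is a comma-separated subset of `AD,AR,XL`;
#' empty cells mean unknown.
#'
#' @param path TSV path.
#' @return Named list of [gene_info] objects keyed by symbol.
#' @export
read_gene_info <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  stopifnot(all(c("symbol", "inheritance") %in% names(tab)))
  opt <- function(x) if (is.null(x) || is.na(x)) NULL else x
  genes <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    inh <- if (is.na(row$inheritance)) character() else
      strsplit(row$inheritance, ",", fixed = TRUE)[[1]]
    gene_info(
      symbol = row$symbol, inheritance = trimws(inh),
      missense_z = opt(row$missense_z),
      benign_nonvus_missense = opt(row$benign_nonvus_missense),
      total_nonvus_missense = opt(row$total_nonvus_missense),
      lof_mechanism = opt(row$lof_mechanism),
      bp1_z_rule = isTRUE(row$bp1_z_rule))
  })
  stats::setNames(genes, tab$symbol)
}

.upstream_call_from_json <- function(x) {
  met <- if (is.null(x$met)) TRUE else isTRUE(x$met)
  strength <- x$strength
  source <- if (is.null(x$source)) "upstream" else x$source
  if (met && identical(x$criterion, "BP6") &&
      !strength %in% c("StandAlone", "Strong", "Supporting")) {
    # off-scale upstream BP6 levels are re-assigned at read time
    return(modify_bp6(TRUE, strength))
  }
  evidence_call(x$criterion, met = met,
                strength = if (met) strength else NULL,
                rationale = if (is.null(x$rationale)) "" else x$rationale,
                source = source)
}

.annotation_from_json <- function(x, genes) {
  parts <- .split_annotation(x$annotation)
  gene <- if (!is.null(x$gene)) {
    do.call(gene_info, x$gene)
  } else if (!is.null(genes[[parts$gene]])) {
    genes[[parts$gene]]
  } else {
    gene_info(parts$gene)
  }
  sc <- if (is.null(x$scores)) predictor_scores() else
    do.call(predictor_scores, x$scores)
  pop <- if (is.null(x$population)) population_data() else
    do.call(population_data, x$population)
  lof <- if (is.null(x$lof)) NULL else do.call(lof_annotation, x$lof)
  cv <- if (is.null(x$clinvar)) NULL else do.call(clinvar_summary, x$clinvar)
  ups <- lapply(x$upstream_calls %||% list(), .upstream_call_from_json)
  variant_annotation(
    sample_id = x$sample_id, panel = x$panel %||% "",
    gene = gene, transcript = parts$transcript, hgvs_c = parts$hgvs_c,
    hgvs_p = x$hgvs_p, consequence = x$consequence %||% "other",
    zygosity = x$zygosity %||% "het", scores = sc, population = pop,
    lof = lof, clinvar = cv, upstream_calls = ups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read annotated variant records
#'
#' JSON Lines (one JSON object per line; the rich schema mapping 1:1 onto
#' [variant_annotation], with the `GENE:NM:c.` string in `annotation`) or
#' CSV (`SAMPLEID,PANEL_NAME,ANNOTATION`, header optional). Malformed rows
#' are collected into `attr(, "errors")` (a data frame of line numbers and
#' messages); valid rows proceed.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @param genes Optional gene table from [read_gene_info], used to attach
#'   gene-level information to records that do not embed their own.
#' @return List of [variant_annotation] objects with attribute `errors`.
#' @export
read_records <- function(path, format = c("auto", "jsonl", "csv"),
                         genes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
      "jsonl"
  }
  lines <- readLines(path, warn = FALSE)
  records <- list()
  errors <- list()
  note <- function(line, msg) {
    errors[[length(errors) + 1L]] <<- data.frame(line = line, message = msg)
  }
  if (format == "jsonl") {
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[i]))) next
      rec <- tryCatch({
        .annotation_from_json(
          jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE),
          genes)
      }, error = function(e) {
        note(i, conditionMessage(e))
        NULL
      })
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  } else {
    start <- 1L
    if (length(lines) &&
        grepl("^\\s*SAMPLEID", lines[1], ignore.case = TRUE)) {
      start <- 2L
    }
    for (i in seq(from = start, length.out = max(0L, length(lines) - start + 1L))) {
      if (!nzchar(trimws(lines[i]))) next
      rec <- tryCatch({
        f <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
        if (length(f) != 3L) {
          stop("expected SAMPLEID,PANEL_NAME,ANNOTATION", call. = FALSE)
        }
        parts <- .split_annotation(f[3])
        gene <- genes[[parts$gene]] %||% gene_info(parts$gene)
        variant_annotation(sample_id = f[1], panel = f[2], gene = gene,
                           transcript = parts$transcript,
                           hgvs_c = parts$hgvs_c)
      }, error = function(e) {
        note(i, conditionMessage(e))
        NULL
      })
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  }
  attr(records, "errors") <- if (length(errors)) {
    do.call(rbind, errors)
  } else {
    data.frame(line = integer(), message = character())
  }
  records
}

.scores_to_json <- function(s) {
  drop_null(list(revel = s$revel, cadd_phred = s$cadd_phred,
                 rank_scores = as.list(s$rank_scores),
                 ada_boost = s$ada_boost, rf = s$rf))
}

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

.annotation_to_json <- function(v) {
  drop_null(list(
    sample_id = v$sample_id, panel = v$panel,
    annotation = variant_label(v), hgvs_p = v$hgvs_p,
    consequence = v$consequence, zygosity = v$zygosity,
    scores = .scores_to_json(v$scores),
    population = drop_null(list(
      maf_by_source = as.list(v$population$maf_by_source),
      gnomad_allele_count = v$population$gnomad_allele_count,
      gnomad_hom_count = v$population$gnomad_hom_count,
      coverage_ok = v$population$coverage_ok)),
    gene = drop_null(list(
      symbol = v$gene$symbol, inheritance = v$gene$inheritance,
      missense_z = v$gene$missense_z,
      benign_nonvus_missense = v$gene$benign_nonvus_missense,
      total_nonvus_missense = v$gene$total_nonvus_missense,
      lof_mechanism = v$gene$lof_mechanism,
      bp1_z_rule = v$gene$bp1_z_rule)),
    lof = if (is.null(v$lof)) NULL else drop_null(unclass(v$lof)),
    clinvar = if (is.null(v$clinvar)) NULL else unclass(v$clinvar),
    upstream_calls = lapply(v$upstream_calls, function(u) {
      drop_null(unclass(u))
    })))
}

#' Write annotation records as JSON Lines
#'
#' Inverse of [read_records] on the JSONL format.
#'
#' @param variants List of [variant_annotation] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(variants, path) {
  lines <- vapply(variants, function(v) {
    jsonlite::toJSON(.annotation_to_json(v), auto_unbox = TRUE,
                     digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a segregation-results table
#'
#' Tab-separated with header `sample_id, gene, hgvs_c, kind, meioses,
#' parentage_confirmed` (and optionally `unaffected_carrier`).
#'
#' @param path TSV path.
#' @return Named list of [segregation_result] keyed by `GENE:hgvs_c`.
#' @export
read_segregation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  stopifnot(all(c("gene", "hgvs_c", "kind") %in% names(tab)))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    out[[paste(row$gene, row$hgvs_c, sep = ":")]] <- segregation_result(
      kind = row$kind,
      meioses = if (!is.null(row$meioses) && !is.na(row$meioses)) {
        row$meioses
      } else NULL,
      parentage_confirmed = isTRUE(row$parentage_confirmed),
      unaffected_carrier = isTRUE(row$unaffected_carrier))
  }
  out
}

.verdict_to_json <- function(entry) {
  v <- entry$verdict
  a <- entry$annotation
  drop_null(list(
    annotation = variant_label(a), panel = a$panel,
    acmg_class = v$acmg_class, vus_subclass = v$vus_subclass,
    reportable = v$reportable,
    evidence = lapply(unname(unclass(v$evidence)), function(call) {
      drop_null(unclass(call))
    }),
    ppot = if (is.null(v$ppot)) NULL else drop_null(unclass(v$ppot)),
    explanation = as.list(v$explanation),
    scores = .scores_to_json(a$scores)))
}

#' Write a classification report
#'
#' Per variant: the annotation, each met criterion with strength and
#' rationale, the final class/subclass, the reportable flag and the
#' predictor scores. JSON reports round-trip through [read_report].
#'
#' @param contexts Named list of [sample_context] objects (as returned by
#'   [classify_annotations]).
#' @param path Output file.
#' @param format `"json"`, `"tsv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(contexts, path, format = c("json", "tsv", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- lapply(contexts, function(ctx) {
      list(sample_id = ctx$sample_id,
           variants = lapply(ctx$variants, .verdict_to_json))
    })
    jsonlite::write_json(unname(payload), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (format == "tsv") {
    rows <- list()
    for (ctx in contexts) {
      for (entry in ctx$variants) {
        v <- entry$verdict
        crit <- vapply(Filter(function(x) x$met, unclass(v$evidence)),
                       function(x) paste0(x$criterion, ":", x$strength), "")
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = ctx$sample_id,
          panel = entry$annotation$panel,
          annotation = variant_label(entry$annotation),
          acmg_class = v$acmg_class, vus_subclass = v$vus_subclass,
          reportable = v$reportable,
          criteria = paste(crit, collapse = ";"))
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(), panel = character(),
                 annotation = character(), acmg_class = character(),
                 vus_subclass = character(), reportable = logical(),
                 criteria = character())
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (ctx in contexts) {
      writeLines(sprintf("== Sample %s ==", ctx$sample_id), con)
      for (entry in ctx$variants) {
        v <- entry$verdict
        writeLines(sprintf("-- %s (%s) --", variant_label(entry$annotation),
                           entry$annotation$panel), con)
        writeLines(paste0("  ", v$explanation), con)
        writeLines(sprintf("  Reportable: %s",
                           if (v$reportable) "yes" else "no"), con)
        sc <- entry$annotation$scores
        if (!is.null(sc$revel)) {
          writeLines(sprintf("  REVEL: %s  CADD: %s", format(sc$revel),
                             format(sc$cadd_phred %||% NA)), con)
        }
        if (!is.null(sc$rank_scores)) {
          writeLines(paste0("  rank scores: ",
                            paste(names(sc$rank_scores),
                                  format(unname(sc$rank_scores)),
                                  sep = "=", collapse = " ")), con)
        }
        writeLines("", con)
      }
    }
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path A JSON report written by [write_report].
#' @return The parsed report structure (list of samples, each with its
#'   variant verdicts).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
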