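#' Reporter gene-array geometries
#'
#' A `gene_model` describes the interval layout of one copy of an MS2-tagged
#' reporter mini-gene in 0-based, half-open bp coordinates: exons, introns,
#' the MS2 stem-loop region in the 3'UTR, the FISH probe targets, and the
#' number of tandem copies in the integrated array. A polymerase "has
#' transcribed" position `x` of the gene once its position is `>= x`.
#'
#' Two presets are packaged: `"E3"`, a beta-globin-style mini-gene with
#' 3 exons and 2 introns, and `"E6"`, the extended variant with 6 exons and
#' 5 introns. Both carry 18 MS2 repeats and share the MS2-region length and
#' per-intron geometry. The source constructs' exact bp lengths are not
#' published, so the packaged segment lengths are documented placeholders on
#' a realistic mini-gene scale; every property of the model that matters
#' downstream is stated relative to the geometry, not to these defaults.
#'
#' @param preset `"E3"` or `"E6"`.
#' @param overrides named list of fields to replace in the preset (e.g.
#'   `list(n_copies = 1)`); the result is re-validated.
#' @return A validated `gene_model` list with fields `name`, `length_bp`,
#'   `exons` and `introns` (two-column start/end matrices), `ms2_region`,
#'   `n_ms2_repeats`, `exon_probe`, `intron_probe_indices`, `n_copies` and
#'   `footprint_bp` (minimum polymerase spacing, default 35 bp).
#' @examples
#' g <- build_gene("E3")
#' nrow(g$introns)  # 2
#' @export
build_gene <- function(preset = c("E3", "E6"), overrides = NULL) {
  presets <- gene_presets()
  if (!is.character(preset) || length(preset) != 1 || !preset %in% names(presets)) {
    stop("unknown gene preset: ", paste(preset, collapse = ", "),
         " (known: ", paste(names(presets), collapse = ", "), ")")
  }
  g <- presets[[preset]]
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    bad <- setdiff(names(overrides), names(g))
    if (length(bad)) stop("unknown gene_model field(s): ", paste(bad, collapse = ", "))
    g[names(overrides)] <- overrides
    g <- normalize_gene_fields(g)
  }
  v <- validate_gene(g)
  if (length(v)) stop("invalid gene model: ", paste(v, collapse = "; "))
  g
}

gene_presets <- function() {
  path <- system.file("extdata", "gene_presets.json", package = "txnfrap")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[setdiff(names(raw), "_comment")]
  lapply(raw, normalize_gene_fields)
}

normalize_gene_fields <- function(g) {
  as_ivl_matrix <- function(x) {
    m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
    m <- matrix(as.numeric(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
    m
  }
  g$exons <- as_ivl_matrix(g$exons)
  g$introns <- as_ivl_matrix(g$introns)
  g$ms2_region <- as.numeric(g$ms2_region)
  g$exon_probe <- as.numeric(g$exon_probe)
  g$intron_probe_indices <- as.integer(g$intron_probe_indices)
  g$length_bp <- as.numeric(g$length_bp)
  g$n_ms2_repeats <- as.integer(g$n_ms2_repeats)
  g$n_copies <- as.integer(g$n_copies)
  if (is.null(g$footprint_bp)) g$footprint_bp <- 35
  g$footprint_bp <- as.numeric(g$footprint_bp)
  class(g) <- "gene_model"
  g
}

fmt_ivl <- function(iv) sprintf("[%g, %g)", iv[1], iv[2])

#' Validate a gene model
#'
#' Checks every structural invariant of a [build_gene()] model and returns
#' all violations, not just the first. The validator never raises.
#'
#' @param g a `gene_model` (or a bare list with the same fields).
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_gene <- function(g) {
  v <- character()
  need <- c("name", "length_bp", "exons", "introns", "ms2_region",
            "n_ms2_repeats", "exon_probe", "intron_probe_indices", "n_copies")
  miss <- setdiff(need, names(g))
  if (length(miss)) return(paste("missing field(s):", paste(miss, collapse = ", ")))

  ok_ivl <- function(iv) length(iv) == 2 && !anyNA(iv) && iv[1] < iv[2]
  in_gene <- function(iv) iv[1] >= 0 && iv[2] <= g$length_bp

  if (!is.numeric(g$length_bp) || length(g$length_bp) != 1 || is.na(g$length_bp) ||
      g$length_bp <= 0) {
    v <- c(v, "length_bp must be a single positive number")
    return(v)
  }
  segs <- rbind(g$exons, g$introns)
  kind <- c(rep("exon", nrow(g$exons)), rep("intron", nrow(g$introns)))
  idx <- c(seq_len(nrow(g$exons)), seq_len(nrow(g$introns)))
  for (i in seq_len(nrow(segs))) {
    iv <- segs[i, ]
    if (!ok_ivl(iv)) {
      v <- c(v, sprintf("%s %d is not a proper half-open interval: %s",
                        kind[i], idx[i], fmt_ivl(iv)))
    } else if (!in_gene(iv)) {
      v <- c(v, sprintf("%s %d %s lies outside [0, %g)", kind[i], idx[i],
                        fmt_ivl(iv), g$length_bp))
    }
  }
  # pairwise disjointness of exons and introns, naming both intervals
  if (nrow(segs) > 1) {
    for (i in seq_len(nrow(segs) - 1)) {
      for (j in seq(i + 1, nrow(segs))) {
        a <- segs[i, ]; b <- segs[j, ]
        if (ok_ivl(a) && ok_ivl(b) && a[1] < b[2] && b[1] < a[2]) {
          v <- c(v, sprintf("%s %d %s overlaps %s %d %s", kind[i], idx[i],
                            fmt_ivl(a), kind[j], idx[j], fmt_ivl(b)))
        }
      }
    }
  }
  # sorted and alternating: exon1 < intron1 < exon2 < ...
  if (nrow(g$exons) != nrow(g$introns) + 1) {
    v <- c(v, sprintf("expected one more exon than introns (got %d exons, %d introns)",
                      nrow(g$exons), nrow(g$introns)))
  } else {
    for (i in seq_len(nrow(g$introns))) {
      if (!(g$exons[i, 2] <= g$introns[i, 1] && g$introns[i, 2] <= g$exons[i + 1, 1])) {
        v <- c(v, sprintf("exon/intron order broken around intron %d %s", i,
                          fmt_ivl(g$introns[i, ])))
      }
    }
  }
  if (!ok_ivl(g$ms2_region) || !in_gene(g$ms2_region)) {
    v <- c(v, sprintf("ms2_region %s must be a proper interval within [0, %g)",
                      fmt_ivl(g$ms2_region), g$length_bp))
  } else if (nrow(g$introns) > 0 && g$ms2_region[1] < max(g$introns[, 2])) {
    v <- c(v, sprintf("ms2_region %s must lie downstream of the last intron (end %g)",
                      fmt_ivl(g$ms2_region), max(g$introns[, 2])))
  }
  if (!ok_ivl(g$exon_probe) || !in_gene(g$exon_probe)) {
    v <- c(v, sprintf("exon_probe %s must be a proper interval within [0, %g)",
                      fmt_ivl(g$exon_probe), g$length_bp))
  }
  if (length(g$intron_probe_indices) &&
      (anyNA(g$intron_probe_indices) ||
       any(g$intron_probe_indices < 1 | g$intron_probe_indices > nrow(g$introns)))) {
    v <- c(v, sprintf("intron_probe_indices must index introns 1..%d", nrow(g$introns)))
  }
  if (is.na(g$n_ms2_repeats) || g$n_ms2_repeats < 1) {
    v <- c(v, "n_ms2_repeats must be >= 1")
  }
  if (is.na(g$n_copies) || g$n_copies < 1) {
    v <- c(v, "n_copies must be >= 1")
  }
  if (is.na(g$footprint_bp) || g$footprint_bp <= 0) {
    v <- c(v, "footprint_bp must be > 0")
  }
  v
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s>  %g bp, %d exons, %d introns, %d MS2 repeats, %d copies\n",
              x$name, x$length_bp, nrow(x$exons), nrow(x$introns),
              x$n_ms2_repeats, x$n_copies))
  cat(sprintf("  ms2_region %s, exon_probe %s, intron probes: %s\n",
              fmt_ivl(x$ms2_region), fmt_ivl(x$exon_probe),
              paste(x$intron_probe_indices, collapse = ",")))
  invisible(x)
}

#' Read and write gene models as JSON
#'
#' Round-trips a [build_gene()] model through a JSON document whose keys
#' mirror the field names, so geometries can be edited outside R.
#'
#' @param g a `gene_model`.
#' @param path file path.
#' @return `write_gene_model` returns `path` invisibly; `read_gene_model`
#'   returns a validated `gene_model`.
#' @export
write_gene_model <- function(g, path) {
  out <- unclass(g)
  out$exons <- apply(g$exons, 1, as.numeric, simplify = FALSE)
  out$introns <- apply(g$introns, 1, as.numeric, simplify = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  g <- normalize_gene_fields(jsonlite::read_json(path, simplifyVector = TRUE))
  v <- validate_gene(g)
  if (length(v)) stop("invalid gene model in ", path, ": ", paste(v, collapse = "; "))
  g
}
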