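# Signature catalogs: SBS96 probability matrices in COSMIC layout.

#' Coerce a catalog to a 96 x S probability matrix
#'
#' Accepts a matrix with 96 rows or a tibble/data.frame with a `channel`
#' column plus one numeric column per signature. Validates that columns are
#' non-negative and sum to 1 (within 1e-6); rows are reordered to the
#' canonical channel order.
#'
#' @param catalog Matrix or data frame as described.
#' @return Numeric 96 x S matrix with rownames set to the channel labels.
#' @export
as_catalog_matrix <- function(catalog) {
  chans <- sbs96_channels()
  if (is.data.frame(catalog)) {
    if (!"channel" %in% names(catalog)) {
      abort("as_catalog_matrix(): data frame catalog needs a 'channel' column")
    }
    m <- as.matrix(catalog[, setdiff(names(catalog), "channel"), drop = FALSE])
    rownames(m) <- catalog$channel
    catalog <- m
  }
  if (!is.matrix(catalog) || nrow(catalog) != 96) {
    abort("as_catalog_matrix(): catalog must have 96 channel rows")
  }
  if (is.null(rownames(catalog))) rownames(catalog) <- chans
  if (!setequal(rownames(catalog), chans)) {
    abort("as_catalog_matrix(): catalog rownames must be the 96 SBS channels")
  }
  catalog <- catalog[chans, , drop = FALSE]
  if (any(catalog < 0)) abort("as_catalog_matrix(): negative entries")
  cs <- colSums(catalog)
  if (any(abs(cs - 1) > 1e-6)) {
    abort("as_catalog_matrix(): signature columns must sum to 1 (+/- 1e-6)")
  }
  catalog
}

#' Read / write a signature catalog TSV
#'
#' The TSV has 96 rows keyed by a `channel` column (`"A[C>A]A"` style) and
#' one column per signature, matching the COSMIC SBS layout.
#'
#' @param path TSV path.
#' @param catalog Matrix or data frame accepted by [as_catalog_matrix()].
#' @return A 96 x S matrix (read) or `path` (write).
#' @export
read_signature_catalog <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_catalog_matrix(df)
}

#' @rdname read_signature_catalog
#' @export
write_signature_catalog <- function(catalog, path) {
  m <- as_catalog_matrix(catalog)
  df <- tibble::tibble(channel = rownames(m)) |>
    dplyr::bind_cols(tibble::as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Build a synthetic signature catalog
#'
#' Generates `n_signatures` distinct sparse SBS96 probability profiles
#' (Dirichlet draws concentrated on a random subset of channels), useful as
#' fixture catalogs where the real COSMIC catalog is a user-supplied input.
#' The first signature is made "clock-like": a flat profile with extra mass
#' on C>T at CpG channels.
#'
#' @param n_signatures Number of signatures.
#' @param seed Integer seed.
#' @param active_channels Number of high-mass channels per signature.
#' @return 96 x S matrix with columns `"SYN1"`, `"SYN2"`, ...
#' @export
synthetic_signature_catalog <- function(n_signatures = 6, seed = 1L,
                                        active_channels = 12L) {
  chans <- sbs96_channels()
  withr::with_seed(seed, {
    m <- sapply(seq_len(n_signatures), function(s) {
      w <- rep(0.05, 96)
      if (s == 1) {
        # clock-like: broad flat profile enriched for C>T at CpG
        cpg <- grepl("\\[C>T\\]G", chans)
        w <- rep(1, 96)
        w[cpg] <- 6
      } else {
        hot <- sample.int(96, active_channels)
        w[hot] <- w[hot] + stats::rgamma(active_channels, shape = 2, rate = 0.5)
      }
      w / sum(w)
    })
    rownames(m) <- chans
    colnames(m) <- paste0("SYN", seq_len(n_signatures))
    m
  })
}

#' Cosine similarity between vectors or matrix columns
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
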