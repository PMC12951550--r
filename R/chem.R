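# RDKit bridge. No R cheminformatics stack is assumed; SMILES
# canonicalization, fragment counting and ECFP fingerprints are delegated
# to python rdkit through a bundled batch helper. Results are cached per
# session so repeated lookups cost one python start-up at most.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- Sys.getenv("PSLSCREEN_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py)) {
    stop("python not found on PATH; the cheminformatics layer needs ",
         "python with rdkit (set PSLSCREEN_PYTHON to override)")
  }
  py
}

# Batched property lookup; returns a list of records aligned with `smiles`.
chem_props <- function(smiles, radius = 2L, n_bits = 2048L,
                       fingerprints = TRUE) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(list())
  key <- paste0(smiles, "|", radius, "|", n_bits, "|", as.integer(fingerprints))
  # NA inputs are parse failures; never send them to the helper
  failure <- list(ok = FALSE, canonical = NULL, n_frags = 0L, bits = list())
  for (k in key[is.na(smiles)]) assign(k, failure, envir = .chem_cache)
  miss <- !vapply(key, exists, logical(1), envir = .chem_cache)
  if (any(miss)) {
    todo <- smiles[miss]
    fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    # I() keeps `smiles` a JSON array even when length 1
    jsonlite::write_json(list(smiles = I(todo), radius = radius,
                              n_bits = n_bits,
                              want_fp = as.integer(fingerprints)),
                         fin, auto_unbox = TRUE)
    script <- system.file("python", "rdkit_tools.py", package = "pslscreen",
                          mustWork = TRUE)
    status <- system2(chem_python(), c(shQuote(script), shQuote(fin),
                                       shQuote(fout)),
                      stdout = FALSE, stderr = "")
    if (!identical(status, 0L) || !file.exists(fout)) {
      stop("rdkit helper failed (status ", status,
           "); is rdkit importable from ", chem_python(), "?")
    }
    res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
    if (length(res) != length(todo)) {
      stop("rdkit helper returned ", length(res), " records for ",
           length(todo), " SMILES")
    }
    for (i in seq_along(todo)) {
      assign(key[miss][i], res[[i]], envir = .chem_cache)
    }
  }
  lapply(key, get, envir = .chem_cache)
}

#' Canonicalize SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @return character vector of RDKit canonical SMILES; `NA` where a string
#'   does not parse.
#' @export
canonical_smiles <- function(smiles) {
  props <- chem_props(smiles, fingerprints = FALSE)
  vapply(props, function(p) if (p$ok) p$canonical else NA_character_,
         character(1))
}

#' Does a SMILES encode multiple disconnected fragments?
#'
#' Mixtures and ionic pairs (e.g. `"[Na+].[Cl-]"`) carry several
#' disconnected molecular entities; the CNS screen excludes them.
#'
#' @param smiles character vector of SMILES.
#' @return logical vector; errors if any string does not parse.
#' @export
is_multifragment <- function(smiles) {
  props <- chem_props(smiles, fingerprints = FALSE)
  bad <- !vapply(props, `[[`, logical(1), "ok")
  if (any(bad)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[bad], 5L), collapse = ", "))
  }
  vapply(props, function(p) p$n_frags > 1L, logical(1))
}

#' Extended-connectivity (Morgan) fingerprint
#'
#' Radius-2, 2048-bit by default (the ECFP4-equivalent community default).
#' Canonical-equivalent SMILES give identical fingerprints.
#'
#' @param smiles a single SMILES string (single-fragment).
#' @param radius Morgan radius (default 2).
#' @param n_bits fingerprint length (default 2048).
#' @return integer 0/1 vector of length `n_bits`.
#' @export
ecfp_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(length(smiles) == 1L)
  ecfp_matrix(smiles, radius, n_bits)[1L, ]
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles character vector of single-fragment SMILES.
#' @inheritParams ecfp_fingerprint
#' @return integer 0/1 matrix, one row per molecule.
#' @export
ecfp_matrix <- function(smiles, radius = 2L, n_bits = 2048L) {
  props <- chem_props(smiles, radius = radius, n_bits = n_bits)
  bad <- !vapply(props, `[[`, logical(1), "ok")
  if (any(bad)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[bad], 5L), collapse = ", "))
  }
  frags <- vapply(props, function(p) p$n_frags, integer(1))
  if (any(frags > 1L)) {
    stop("multi-fragment SMILES cannot be fingerprinted: ",
         paste(utils::head(smiles[frags > 1L], 5L), collapse = ", "))
  }
  X <- matrix(0L, length(smiles), n_bits)
  for (i in seq_along(props)) {
    bits <- unlist(props[[i]]$bits)
    if (length(bits)) X[i, bits + 1L] <- 1L
  }
  rownames(X) <- names(smiles)
  X
}
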