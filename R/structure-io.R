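# Coordinate I/O and nomenclature normalization.
#
# A structure_ensemble holds every atom of every model in one data.frame
# (columns: model, chain, seq_index, res_name, base_type, variant, atom,
# element, x, y, z) plus a source id. All models must share the same ordered
# residue list; this is validated on construction.

#' Construct a structure ensemble
#'
#' @param atoms data.frame with columns model, chain, seq_index, res_name,
#'   atom, element, x, y, z (base_type/variant added by
#'   [normalize_nomenclature()] and defaulted to "other"/"unknown" here).
#' @param source_id free-text identifier (file name, PDB id, preset name).
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, source_id = "unknown") {
  need <- c("model", "chain", "seq_index", "res_name", "atom", "element",
            "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0) {
    stop("atoms is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("ensemble must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in ensemble")
  }
  if (any(!nzchar(atoms$atom))) stop("empty atom names in ensemble")
  if (is.null(atoms$base_type)) atoms$base_type <- "other"
  if (is.null(atoms$variant)) atoms$variant <- "unknown"
  atoms$model <- as.integer(atoms$model)
  atoms$seq_index <- as.integer(atoms$seq_index)
  obj <- list(atoms = atoms, source_id = source_id)
  class(obj) <- "structure_ensemble"
  .validate_models(obj)
  obj
}

.residue_key <- function(df) paste(df$chain, df$seq_index, df$res_name, sep = "|")

.validate_models <- function(ens) {
  a <- ens$atoms
  models <- sort(unique(a$model))
  ref <- NULL
  for (m in models) {
    am <- a[a$model == m, ]
    key <- unique(.residue_key(am))
    if (is.null(ref)) {
      ref <- key
    } else if (!identical(key, ref)) {
      bad <- c(setdiff(key, ref), setdiff(ref, key))
      if (length(bad) == 0) bad <- key[key != ref][1]
      stop("models have mismatched residue lists; first offending residue: ",
           bad[1], " (model ", m, ")")
    }
  }
  invisible(ens)
}

#' Number of models in an ensemble
#' @param ensemble a [structure_ensemble].
#' @export
n_models <- function(ensemble) length(unique(ensemble$atoms$model))

#' Ordered residue list (shared by all models)
#'
#' @param ensemble a [structure_ensemble].
#' @return data.frame with chain, seq_index, res_name, base_type, variant in
#'   file order.
#' @export
residue_table <- function(ensemble) {
  a <- ensemble$atoms
  a1 <- a[a$model == min(a$model), ]
  idx <- !duplicated(.residue_key(a1))
  out <- a1[idx, c("chain", "seq_index", "res_name", "base_type", "variant")]
  rownames(out) <- NULL
  out
}

#' Extract one residue of one model
#'
#' @param ensemble a [structure_ensemble].
#' @param model model index.
#' @param seq_index residue sequence index as in the source file.
#' @param chain chain id; defaults to the first chain carrying that index.
#' @return object of class `g4_residue`: list(chain, seq_index, res_name,
#'   base_type, variant, atoms) where `atoms` is a matrix with atom-name
#'   rownames and x/y/z columns.
#' @export
get_residue <- function(ensemble, model, seq_index, chain = NULL) {
  a <- ensemble$atoms
  sel <- a$model == model & a$seq_index == seq_index
  if (!is.null(chain)) sel <- sel & a$chain == chain
  r <- a[sel, ]
  if (nrow(r) == 0) {
    stop("no residue with seq_index ", seq_index, " in model ", model)
  }
  if (length(unique(r$chain)) > 1) r <- r[r$chain == r$chain[1], ]
  X <- as.matrix(r[, c("x", "y", "z")])
  rownames(X) <- r$atom
  out <- list(chain = r$chain[1], seq_index = seq_index,
              res_name = r$res_name[1], base_type = r$base_type[1],
              variant = r$variant[1], atoms = X)
  class(out) <- "g4_residue"
  out
}

# fetch coordinates of one atom, or NULL if absent
.atom_xyz <- function(ensemble, model, seq_index, atom, chain = NULL) {
  a <- ensemble$atoms
  sel <- a$model == model & a$seq_index == seq_index & a$atom == atom
  if (!is.null(chain)) sel <- sel & a$chain == chain
  r <- a[sel, ]
  if (nrow(r) == 0) return(NULL)
  c(r$x[1], r$y[1], r$z[1])
}

#' Read a multi-model coordinate file
#'
#' Parses PDB (fixed-width ATOM/HETATM/MODEL records) or mmCIF
#' (`_atom_site` loop) files. Alternate locations are resolved to the highest
#' occupancy; star atom names (C1*) are normalized to primes (C1') on read.
#'
#' @param path file path.
#' @param format one of "auto", "pdb", "mmcif". "auto" decides from the file
#'   extension (.cif/.mmcif) and content.
#' @param chain optional chain filter (only the given chains are kept).
#' @return a [structure_ensemble]; nomenclature is normalized with the default
#'   alias table (see [normalize_nomenclature()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
    if (format == "pdb") {
      head1 <- readLines(path, n = 5L, warn = FALSE)
      if (any(grepl("^data_|^loop_|^_atom_site", head1))) format <- "mmcif"
    }
  }
  atoms <- if (format == "pdb") .read_pdb(path) else .read_mmcif(path)
  if (nrow(atoms) == 0) stop("no coordinates parsed from ", path)
  if (!is.null(chain)) {
    atoms <- atoms[atoms$chain %in% chain, ]
    if (nrow(atoms) == 0) stop("chain filter removed all atoms")
  }
  atoms <- .resolve_altloc(atoms)
  atoms$altloc <- NULL
  atoms$occupancy <- NULL
  ens <- structure_ensemble(atoms, source_id = basename(path))
  normalize_nomenclature(ens)
}

.read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_no <- 0L
  cur <- 1L
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  model_col <- integer(length(lines))
  for (i in seq_along(lines)) {
    if (is_model[i]) {
      model_no <- model_no + 1L
      mn <- suppressWarnings(as.integer(substr(lines[i], 7, 14)))
      cur <- if (!is.na(mn)) mn else model_no
    }
    model_col[i] <- cur
  }
  al <- lines[is_atom]
  if (length(al) == 0) {
    return(data.frame(model = integer(0), chain = character(0),
                      seq_index = integer(0), res_name = character(0),
                      atom = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  f <- function(from, to) trimws(substr(al, from, to))
  name <- f(13, 16)
  name <- gsub("\\*", "'", name)
  elem <- f(77, 78)
  guess <- substr(gsub("[^A-Za-z].*$", "", name), 1, 1)
  elem <- ifelse(nzchar(elem), elem, guess)
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    model = model_col[is_atom],
    chain = ifelse(nzchar(f(22, 22)), f(22, 22), "A"),
    seq_index = as.integer(f(23, 26)),
    res_name = f(18, 20),
    atom = name,
    element = toupper(elem),
    altloc = f(17, 17),
    occupancy = occ,
    x = as.numeric(f(31, 38)),
    y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    stringsAsFactors = FALSE)
}

# minimal mmCIF _atom_site reader (standard wwPDB column names)
.read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  n <- length(lines)
  cols <- character(0)
  rows <- character(0)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      hdr <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        hdr <- c(hdr, trimws(lines[j])); j <- j + 1L
      }
      if (length(hdr) > 0 && all(grepl("^_atom_site\\.", hdr))) {
        cols <- sub("^_atom_site\\.", "", hdr)
        while (j <= n && !grepl("^\\s*(loop_|_|#|data_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows <- c(rows, lines[j]); j <- j + 1L
        }
        break
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(cols) == 0) stop("no _atom_site loop found in mmCIF file")
  toks <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(toks, length, integer(1)) != length(cols))
  if (length(bad) > 0) stop("malformed _atom_site row ", bad[1])
  M <- do.call(rbind, toks)
  colnames(M) <- cols
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% cols) return(M[, nm])
    rep(NA_character_, nrow(M))
  }
  # strip only matched quote pairs; a lone trailing prime (C4') is data
  unq <- function(x) {
    n <- nchar(x)
    q <- n >= 2 & substr(x, 1, 1) == substr(x, n, n) &
      substr(x, 1, 1) %in% c("'", "\"")
    x[q] <- substr(x[q], 2, n[q] - 1)
    x
  }
  name <- gsub("\\*", "'", unq(pick("label_atom_id", "auth_atom_id")))
  mdl <- pick("pdbx_PDB_model_num")
  if (all(is.na(mdl))) mdl <- "1"
  data.frame(
    model = as.integer(mdl),
    chain = unq(pick("auth_asym_id", "label_asym_id")),
    seq_index = as.integer(pick("auth_seq_id", "label_seq_id")),
    res_name = unq(pick("label_comp_id", "auth_comp_id")),
    atom = name,
    element = toupper(unq(pick("type_symbol"))),
    altloc = gsub("[.?]", "", pick("label_alt_id")),
    occupancy = {
      o <- suppressWarnings(as.numeric(pick("occupancy")))
      o[is.na(o)] <- 1; o
    },
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    stringsAsFactors = FALSE)
}

# keep the highest-occupancy alternate location per (model, residue, atom),
# preserving file order otherwise
.resolve_altloc <- function(atoms) {
  if (is.null(atoms$altloc)) return(atoms)
  atoms$.ord <- seq_len(nrow(atoms))
  key <- paste(atoms$model, atoms$chain, atoms$seq_index, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occupancy)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(key[ord]), ]
  atoms <- atoms[order(atoms$.ord), ]
  atoms$.ord <- NULL
  atoms
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a [structure_ensemble].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ensemble, path) {
  a <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   generated by quadfold (%s)", ensemble$source_id),
             con)
  for (m in sort(unique(a$model))) {
    am <- a[a$model == m, ]
    writeLines(sprintf("MODEL     %4d", m), con)
    nm <- am$atom
    # PDB name field: element right-aligned into cols 13-14 for short names
    fmt_name <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
    lines <- sprintf(
      "ATOM  %5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(am)), fmt_name, substr(am$res_name, 1, 3), am$chain,
      am$seq_index, am$x, am$y, am$z, 1, 0, substr(am$element, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Default residue and atom alias table
#'
#' Loaded from `inst/extdata/residue_aliases.tsv` (editable data, not code).
#' Maps residue names to (base_type, variant) and atom-name synonyms to
#' canonical primed names. The 2'-modified guanosine codes follow common
#' conventions but have not been validated against the live PDB chemical
#' component dictionary; extend the table for entry-specific codes.
#'
#' @return list with data.frames `residues` (name, base_type, variant) and
#'   `atoms` (from, to).
#' @export
default_aliases <- function() {
  path <- system.file("extdata", "residue_aliases.tsv", package = "quadfold")
  if (!nzchar(path)) stop("alias table not found; broken installation?")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  res <- tab[tab$kind == "residue", c("from", "base_type", "variant")]
  names(res)[1] <- "name"
  atm <- tab[tab$kind == "atom", c("from", "to")]
  list(residues = res, atoms = atm)
}

#' Normalize residue and atom nomenclature
#'
#' Resolves base type and sugar variant for every residue from an alias table
#' and rewrites atom-name synonyms (e.g. O1' -> O4', star forms -> primes).
#' Unknown residue names pass through with base_type "other", variant
#' "unknown", and a warning.
#'
#' @param ensemble a [structure_ensemble].
#' @param aliases alias table as returned by [default_aliases()].
#' @return the normalized [structure_ensemble].
#' @export
normalize_nomenclature <- function(ensemble, aliases = default_aliases()) {
  a <- ensemble$atoms
  a$atom <- gsub("\\*", "'", a$atom)
  m <- match(a$atom, aliases$atoms$from)
  hit <- !is.na(m)
  a$atom[hit] <- aliases$atoms$to[m[hit]]
  rm <- match(a$res_name, aliases$residues$name)
  known <- !is.na(rm)
  a$base_type <- ifelse(known, aliases$residues$base_type[rm], "other")
  a$variant <- ifelse(known, aliases$residues$variant[rm], "unknown")
  unk <- unique(a$res_name[!known])
  if (length(unk) > 0) {
    warning("unknown residue name(s), passed through as (other, unknown): ",
            paste(unk, collapse = ", "))
  }
  ensemble$atoms <- a
  .validate_models(ensemble)
  ensemble
}
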