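# Report serialization: JSON and TSV with stable key order, angles in
# degrees, distances in Angstrom.

#' Write an analysis report
#'
#' JSON output uses stable (construction) key order and unboxed scalars; TSV
#' output expects a data.frame. Serializing the same report twice yields
#' byte-identical files.
#'
#' @param report a named list (json) or data.frame (tsv).
#' @param path output file path.
#' @param format "json" or "tsv".
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  if (format == "json") {
    txt <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 8,
                            pretty = TRUE, null = "null", na = "null")
    writeLines(txt, path)
  } else {
    if (!is.data.frame(report)) stop("tsv format requires a data.frame")
    df <- report
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, format = "g",
                                                   digits = 8))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# JSON-friendly rendering of a g4_topology object
.topology_report <- function(topo) {
  if (isTRUE(topo$empty)) {
    return(list(model = topo$model, n_tetrads = length(topo$tetrads),
                tetrads = list(), interfaces = list(), columns = list(),
                grooves = list(), loops = list(), vloops = list(),
                config = topo$config))
  }
  cyc <- vapply(topo$stack$layers, function(x) paste(x, collapse = ">"),
                character(1))
  cols <- lapply(topo$columns, function(cl) {
    list(residues = cl$residues, orientation = cl$orientation,
         broken = cl$broken,
         inversions = lapply(cl$inversions, identity))
  })
  vl <- lapply(topo$vloops, function(v) {
    list(anchor5 = v$anchor5, anchor3 = v$anchor3,
         n_intervening = v$n_intervening,
         chi5 = v$chi5$cls, chi3 = v$chi3$cls,
         chi5_deg = v$chi5$chi, chi3_deg = v$chi3$chi,
         P5_deg = v$pucker5$P, P3_deg = v$pucker3$P,
         pucker5 = v$pucker5$octant, pucker3 = v$pucker3$octant,
         turn_locus = v$turn_locus)
  })
  list(model = topo$model,
       n_tetrads = length(topo$tetrads),
       tetrads = as.list(cyc),
       interfaces = as.list(topo$stack$interfaces),
       columns = cols,
       grooves = topo$grooves,
       loops = topo$loops,
       vloops = vl,
       config = topo$config)
}
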