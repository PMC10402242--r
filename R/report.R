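## Report writing: TSV tables, text fragment maps, level summary.

#' Write the reports for a result bundle
#'
#' Emits `complexoforms.tsv` (ranked candidates), `proteoforms.tsv`
#' (characterizations), `matches.tsv` (fragment matches),
#' `observed_only.tsv`, `maps.txt` (one text fragment map per characterized
#' proteoform) and `summary.txt` (counts per characterization level and
#' tier). An empty bundle yields headers-only tables.
#'
#' @param bundle A result bundle from [runPipeline()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
writeReports <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wt <- function(tab, name) {
    pth <- file.path(dir, name)
    utils::write.table(tab, pth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, pth)
  }
  wt(bundle$identifications, "complexoforms.tsv")

  chtab <- .characterizationTable(bundle)
  wt(chtab, "proteoforms.tsv")

  mrows <- lapply(bundle$characterizations, function(ch) {
    if (!nrow(ch$matches)) return(NULL)
    cbind(spectrum_id = ch$spectrum_id, ch$matches)
  })
  mtab <- if (length(mrows)) do.call(rbind, mrows) else
    cbind(data.frame(spectrum_id = character(0)),
          .emptyLadder(),
          data.frame(observed_mass = numeric(0), ppm_error = numeric(0),
                     obs_idx = integer(0)))
  wt(mtab, "matches.tsv")
  wt(bundle$observedOnly, "observed_only.tsv")

  maps <- vapply(bundle$characterizations, function(ch)
    paste0("## ", ch$spectrum_id, " ", ch$protein, " ",
           ch$proteoform_text, "\n", ch$map, "\n"), "")
  writeLines(paste(maps, collapse = "\n"), file.path(dir, "maps.txt"))
  paths <- c(paths, file.path(dir, "maps.txt"))

  lv <- table(factor(chtab$level, levels = c("1", "2A", "2B", "3", "4", "5")))
  tiers <- table(bundle$identifications$tier)
  summ <- c(sprintf("complexoform candidate rows: %d",
                    nrow(bundle$identifications)),
            sprintf("characterized proteoforms: %d", nrow(chtab)),
            paste0("level ", names(lv), ": ", as.integer(lv)),
            if (length(tiers)) paste0("tier ", names(tiers), ": ",
                                      as.integer(tiers)),
            sprintf("observed-mass-only records: %d",
                    nrow(bundle$observedOnly)))
  writeLines(summ, file.path(dir, "summary.txt"))
  paths <- c(paths, file.path(dir, "summary.txt"))
  invisible(paths)
}

.characterizationTable <- function(bundle) {
  rows <- lapply(bundle$characterizations, function(ch) {
    locs <- vapply(ch$localization, function(l)
      paste0(l$name, ":", l$status,
             if (length(l$sites)) paste0("@", paste(l$sites, collapse = "/"))
             else ""), "")
    mets <- vapply(names(ch$metal_intervals), function(m) {
      mi <- ch$metal_intervals[[m]]
      paste0(m, ":", mi$status,
             if (!is.null(mi$interval))
               paste0("@", mi$interval[1], "-", mi$interval[2]) else "")
    }, "")
    data.frame(spectrum_id = ch$spectrum_id, protein = ch$protein,
               proteoform = ch$proteoform_text,
               monomer_mass = ch$monomer_mass,
               mass_error_da = ch$mass_error_da,
               p_score = ch$p_score, coverage = ch$coverage,
               n_matches = nrow(ch$matches), level = ch$level,
               n_candidates = ch$n_candidates,
               localization = paste(locs, collapse = ";"),
               metal_sites = paste(mets, collapse = ";"))
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(0), protein = character(0),
               proteoform = character(0), monomer_mass = numeric(0),
               mass_error_da = numeric(0), p_score = numeric(0),
               coverage = numeric(0), n_matches = integer(0),
               level = character(0), n_candidates = integer(0),
               localization = character(0), metal_sites = character(0))
}
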