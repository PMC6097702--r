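#' Default 30-region catalogue
#'
#' A representative catalogue of 30 rat brain regions spanning the six
#' anatomical systems commonly quantified in contextual-fear-conditioning
#' co-activation studies: amygdalar nuclei, dorsal and ventral hippocampus,
#' parahippocampal cortices, prefrontal cortices and retrosplenial cortices.
#' Exactly three regions (dCA1, dCA3, dDG) are flagged as belonging to the
#' dorsal hippocampus; dropping them yields the 27-region node set used when a
#' lesioned group lacks those structures.
#'
#' The catalogue is a reconstruction assembled from the abbreviations named in
#' the published analyses, completed with anatomically plausible members of
#' the same systems; it is not a verbatim copy of any published table. Users
#' with their own parcellation should supply their own catalogue in the same
#' format.
#'
#' @return A data.frame with columns `abbreviation`, `full_name`, `system`
#'   (one of `"amygdalar"`, `"dorsal-hippocampal"`, `"ventral-hippocampal"`,
#'   `"parahippocampal"`, `"prefrontal"`, `"retrosplenial"`) and the logical
#'   `in_dorsal_hippocampus`.
#' @export
#' @examples
#' cat30 <- default_region_catalogue()
#' nrow(cat30)                      # 30
#' sum(cat30$in_dorsal_hippocampus) # 3
default_region_catalogue <- function() {
  df <- rbind(
    data.frame(
      abbreviation = c("BLA", "BLP", "BLV", "LADL", "LAVL", "LAVM",
                       "CeC", "CeL", "CeM"),
      full_name = c("basolateral amygdala, anterior",
                    "basolateral amygdala, posterior",
                    "basolateral amygdala, ventral",
                    "lateral amygdala, dorsolateral",
                    "lateral amygdala, ventrolateral",
                    "lateral amygdala, ventromedial",
                    "central amygdala, capsular",
                    "central amygdala, lateral",
                    "central amygdala, medial"),
      system = "amygdalar"),
    data.frame(
      abbreviation = c("dCA1", "dCA3", "dDG"),
      full_name = c("dorsal CA1", "dorsal CA3", "dorsal dentate gyrus"),
      system = "dorsal-hippocampal"),
    data.frame(
      abbreviation = c("vCA1", "vCA3", "vDG", "vSub"),
      full_name = c("ventral CA1", "ventral CA3", "ventral dentate gyrus",
                    "ventral subiculum"),
      system = "ventral-hippocampal"),
    data.frame(
      abbreviation = c("Per_36", "Per_35", "Por", "DLE", "DIE", "MEnt"),
      full_name = c("perirhinal cortex, area 36", "perirhinal cortex, area 35",
                    "postrhinal cortex", "dorsolateral entorhinal cortex",
                    "dorsal intermediate entorhinal cortex",
                    "medial entorhinal cortex"),
      system = "parahippocampal"),
    data.frame(
      abbreviation = c("IL", "PrL", "Cg1", "Cg2", "MO"),
      full_name = c("infralimbic cortex", "prelimbic cortex",
                    "cingulate cortex, area 1", "cingulate cortex, area 2",
                    "medial orbital cortex"),
      system = "prefrontal"),
    data.frame(
      abbreviation = c("RSC", "RSGd", "RSGv"),
      full_name = c("retrosplenial disgranular cortex",
                    "retrosplenial granular cortex, dorsal",
                    "retrosplenial granular cortex, ventral"),
      system = "retrosplenial")
  )
  df$in_dorsal_hippocampus <- df$system == "dorsal-hippocampal"
  validate_region_catalogue(df)
}

#' Validate a region catalogue
#'
#' @param catalogue data.frame with at least `abbreviation`, `system` and
#'   `in_dorsal_hippocampus` columns.
#' @return the catalogue, invisibly unchanged, or an error.
#' @export
validate_region_catalogue <- function(catalogue) {
  stopifnot(is.data.frame(catalogue))
  req <- c("abbreviation", "system", "in_dorsal_hippocampus")
  miss <- setdiff(req, names(catalogue))
  if (length(miss) > 0)
    stop("region catalogue lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(catalogue$abbreviation))
    stop("region catalogue has duplicated abbreviations")
  if (!is.logical(catalogue$in_dorsal_hippocampus))
    stop("in_dorsal_hippocampus must be logical")
  catalogue
}

# Case-insensitive match of region labels against a catalogue.
# Returns canonical abbreviations; unknown labels raise an error that names
# the offending label.
match_regions <- function(labels, catalogue) {
  idx <- match(tolower(labels), tolower(catalogue$abbreviation))
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown region name(s): ", paste(bad, collapse = ", "))
  }
  catalogue$abbreviation[idx]
}
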