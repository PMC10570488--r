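# Default-mode-network naming shared by all modules.

TRACT_NAMES  <- c("CING", "CING_Hippo", "SLF", "IFOF")
REGION_NAMES <- c("PCC", "MTL", "IPL", "MPFC")

#' Tract-to-region pairing of the default mode network
#'
#' Each white-matter fiber tract is paired with the DMN cortical region it
#' projects to: the cingulum (CING) with the posterior cingulate cortex (PCC),
#' the cingulum-hippocampus tract (CING_Hippo) with the medial temporal lobe
#' (MTL), the superior longitudinal fasciculus (SLF) with the inferior parietal
#' lobule (IPL), and the inferior fronto-occipital fasciculus (IFOF) with the
#' medial prefrontal cortex (MPFC).
#'
#' @return A data.frame with columns `tract` and `region`, one row per pair.
#' @export
dmn_pairings <- function() {
  data.frame(
    tract  = TRACT_NAMES,
    region = REGION_NAMES,
    stringsAsFactors = FALSE
  )
}

#' Composite-ROI composition of the DMN cortical regions
#'
#' Maps each DMN region to the cortical parcellation labels whose union forms
#' its composite ROI: MPFC is rostral + caudal anterior cingulate + medial
#' orbitofrontal, MTL is entorhinal + parahippocampal, while PCC and IPL each
#' correspond to a single parcellation label.
#'
#' @return Named list: region name -> character vector of parcellation label
#'   names.
#' @export
dmn_composition <- function() {
  list(
    PCC  = "posterior_cingulate",
    MTL  = c("entorhinal", "parahippocampal"),
    IPL  = "inferior_parietal",
    MPFC = c("rostral_anterior_cingulate", "caudal_anterior_cingulate",
             "medial_orbitofrontal")
  )
}

# run a block with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic child seeds below 2^31, derived from one master seed
derive_seeds <- function(seed, n) {
  (as.double(seed) * 2654435761 + 97 * seq_len(n)) %% 2147483629
}
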