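#' Score fusion schemes on an image pair
#'
#' Runs [fuse_images()] once per requested scheme and reports the energy of
#' image gradient ([eog()]) of each fused result, one row per scheme. A
#' sharper fusion — more of both sources' detail retained — scores higher;
#' only the ranking across schemes is meaningful, not the absolute numbers.
#'
#' @param imgA,imgB Co-registered images in \[0, 1\].
#' @param schemes Character vector of schemes to evaluate.
#' @param cfg Base [fusion_config()]; its `scheme` field is overridden per
#'   row.
#' @return `data.frame` with columns `scheme` and `eog`.
#' @export
fusion_metrics <- function(imgA, imgB,
                           schemes = c("wa", "cgm", "patch_tensor"),
                           cfg = fusion_config()) {
  vals <- vapply(schemes, function(s) {
    cfg$scheme <- s
    eog(fuse_images(imgA, imgB, cfg))
  }, numeric(1))
  data.frame(scheme = schemes, eog = unname(vals),
             stringsAsFactors = FALSE, row.names = NULL)
}
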