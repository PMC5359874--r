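#!/usr/bin/env Rscript

# One-time download of the study's published data files (figshare
# doi:10.6084/m9.figshare.3120130.v3) into inst/extdata/figshare/, under
# the role-based names the download-dependent acceptance tests expect.
# Requires network access; nothing in the test suite runs this script.
#
#   Rscript scripts/fetch_study_data.R
#
# After downloading, inspect the archive contents and save/rename the
# relevant files as:
#
#   amphidiscophora_morphology.nex            (Additional file 1: 13 taxa x 29 characters)
#   hexasterophora_morphology.nex             (Additional file 2: 114 taxa x 108 characters)
#   supermatrix.nex                           (Additional file 9: 73 taxa x 4806 bp, 4 partitions)
#   total_evidence_amphidiscophora.nex        (combined molecular + morphology matrix)
#   total_evidence_hexasterophora.nex         (combined molecular + morphology matrix)
#   asr_matrix_extended.nex                   (Additional file 13: 124 + 6 characters, 125 taxa + outgroup)
#   amphidiscophora_mp_tree.nex               (the single morphology MPT)
#   hexasterophora_mp_trees.nex               (the 46 morphology MPTs / strict consensus)
#   amphidiscophora_total_evidence_tree.nex   (the single total-evidence MPT)
#   hexasterophora_total_evidence_trees.nex   (the 9 total-evidence MPTs)
#   combined_tree.nex                         (the manually grafted two-subclass tree from Additional file 13)

article <- "3120130"
dest <- file.path("inst", "extdata", "figshare")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)

listing_url <- sprintf("https://api.figshare.com/v2/articles/%s/files",
                       article)
message("querying ", listing_url)
listing <- tryCatch(jsonlite::fromJSON(listing_url),
                    error = function(e) {
                      stop("could not reach figshare (offline?): ",
                           conditionMessage(e), call. = FALSE)
                    })
for (i in seq_len(nrow(listing))) {
  f <- file.path(dest, listing$name[i])
  if (file.exists(f)) next
  message("downloading ", listing$name[i])
  utils::download.file(listing$download_url[i], f, mode = "wb",
                       quiet = TRUE)
}
message("done; now rename/extract the files as listed in the header ",
        "comment of this script")
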