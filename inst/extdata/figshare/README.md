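Place the study's published data files here (one-time download; see
scripts/fetch_study_data.R in the repository root for the figshare DOI
and the expected role-based file names). The download-dependent
acceptance tests read this directory; they fail with a pointer to the
fetch script while it is empty.
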