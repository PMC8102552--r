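Package: novexon
Title: Novel Exon Discovery, Differential Splicing and NMD Consequence
    Analysis for Staged RNA-Seq
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nominates novel intron-internal exons from per-base splice
    acceptor/donor score tracks and classifies them into constitutive,
    alternative and reject score bands; estimates percent spliced in (PSI)
    from junction read counts with a conjugate beta-binomial model; calls
    differential splicing between ordered cell stages with a
    shared-versus-independent PSI Bayes factor; classifies alternative
    splicing events (skipped exon, retained intron, alternative 5'/3'
    splice site, mutually exclusive exons) from transcript pairs;
    annotates the coding consequence of novel exon inclusion (premature
    termination codons, in-frame insertions, frameshifts, protein domain
    loss); predicts nonsense-mediated decay (NMD) sensitivity by the
    50-nt last-junction rule and estimates stage-wise NMD efficiency from
    translation-inhibitor assays.  A fully seeded synthetic-data
    generator emulates a five-stage male germ-cell differentiation
    series, including an Mga-like gene whose 18th-intron 145-nt exon adds
    five codons followed by an in-frame stop.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
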