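Package: fallwatch
Title: Human Fall Detection in Colour and Infrared Video via
    Accumulative-Computation Segmentation and Fuzzy Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising human falls in numbered colour or
    infrared frame sequences. Moving-person silhouettes are segmented with
    a lateral-inhibition accumulative-computation (LIAC) engine: per-band
    charge memories saturate where a pixel changes intensity band, decay
    elsewhere, are reinforced by 4-connected lateral propagation from
    saturated pixels, homogenised over connected components, and fused
    across bands and channels. Cleaned masks yield one person bounding box
    per frame; non-overlapping fall-time windows of boxes are reduced to
    six geometric and kinematic indicators (width-to-height ratio, height
    change, horizontal and vertical velocity ratios, fall direction,
    position change), which a Mamdani fuzzy inference system turns into a
    defuzzified fall score, a seven-way fall-pattern label, and post-fall
    inactivity alarms. Includes a deterministic synthetic-scene generator
    for end-to-end testing without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
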