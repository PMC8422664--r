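Package: equisync
Title: Horse-Rider Movement Synchronization Analysis for Hippotherapy IMU Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the movement interaction between a horse and
    a mounted rider during physical therapy sessions that incorporate equine
    movement (hippotherapy). Reads paired inertial-measurement-unit (IMU) logs
    from the horse's back and the rider's head, aligns them on a shared
    push-button sync pulse, and reduces each session to vertical-acceleration
    (ACCz) synchronization metrics: the maximum lagged normalized
    cross-correlation, the time shift at that maximum, and the root-mean-square
    error between the dominant gait-harmonic frequencies of the two spectra.
    Also summarises Timed Up and Go and 10-Meter Walk Test timings across
    sessions as percent changes and group variability. A coupled horse-rider
    gait simulator generates session series with known lag, coupling and
    progression for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
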