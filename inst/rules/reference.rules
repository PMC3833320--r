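# Reference rule base for the fall detector.
#
# YES votes: a HIGH height change with non-negligible velocity (standing
# falls; the OR over the two velocities is encoded as two conjunctive
# rules), a lying-shaped box reached through a non-trivial height change
# (sitting falls), or a lying-shaped box whose corner rose (falls from a
# lying position, e.g. out of bed).
IF HeightChange IS HIGH AND HorizontalVelocity IS NOT LOW THEN Fall IS YES
IF HeightChange IS HIGH AND VerticalVelocity IS NOT LOW THEN Fall IS YES
IF WidthToHeightRatio IS HIGH AND HeightChange IS NOT LOW THEN Fall IS YES
IF WidthToHeightRatio IS HIGH AND PositionChange IS 1 THEN Fall IS YES

# NO votes: no height change at all, or a moderate change at low velocities
# with a non-lying box (kneeling/crouching false falls).
IF HeightChange IS LOW AND WidthToHeightRatio IS NOT HIGH THEN Fall IS NO
IF HeightChange IS MEDIUM AND HorizontalVelocity IS LOW AND VerticalVelocity IS LOW AND WidthToHeightRatio IS NOT HIGH THEN Fall IS NO
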