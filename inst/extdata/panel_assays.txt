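hsa-let-7b
hsa-let-7d*
hsa-let-7f
hsa-let-7g
hsa-let-7i
hsa-miR-101
hsa-miR-103
hsa-miR-106a
hsa-miR-107
hsa-miR-122
hsa-miR-125b
hsa-miR-126
hsa-miR-126*
hsa-miR-139-5p
hsa-miR-140-3p
hsa-miR-140-5p
hsa-miR-142-3p
hsa-miR-142-5p
hsa-miR-143
hsa-miR-144
hsa-miR-145
hsa-miR-146a
hsa-miR-148a
hsa-miR-148b
hsa-miR-150
hsa-miR-151-3p
hsa-miR-151-5p
hsa-miR-152
hsa-miR-15a
hsa-miR-15b
hsa-miR-16
hsa-miR-17
hsa-miR-181a
hsa-miR-185
hsa-miR-186
hsa-miR-18a
hsa-miR-191
hsa-miR-192
hsa-miR-197
hsa-miR-1979
hsa-miR-199a-3p
hsa-miR-199a-5p
hsa-miR-19b
hsa-miR-20a
hsa-miR-21
hsa-miR-22
hsa-miR-221
hsa-miR-222
hsa-miR-223
hsa-miR-23a
hsa-miR-23b
hsa-miR-24
hsa-miR-25
hsa-miR-26a
hsa-miR-26b
hsa-miR-27a
hsa-miR-27b
hsa-miR-29a
hsa-miR-29c
hsa-miR-30b
hsa-miR-30c
hsa-miR-30e
hsa-miR-320a
hsa-miR-320b
hsa-miR-324-3p
hsa-miR-335
hsa-miR-338-3p
hsa-miR-342-3p
hsa-miR-374b
hsa-miR-378
hsa-miR-423-3p
hsa-miR-423-5p
hsa-miR-424
hsa-miR-425
hsa-miR-425*
hsa-miR-451
hsa-miR-484
hsa-miR-486-5p
hsa-miR-505
hsa-miR-590-5p
hsa-miR-652
hsa-miR-92a
hsa-miR-93
hsa-miR-99a
hsa-miR-99b
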