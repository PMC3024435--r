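{
  "comment": "Synthetic schematic atlas for tests and demonstrations: rectangular stand-in polygons named after the major dorsal cortical regions, in abstract atlas units with the anterior-posterior axis along rows and the midline at col 0. Gaps between polygons are intentional; pixels in gaps stay unassigned. Landmarks: olfactory bulb / cerebrum junction, then the cerebrum / superior colliculus fissure (lambda), both on the midline. This file is not a digitized histological atlas.",
  "landmarks": [[15, 0], [85, 0]],
  "regions": {
    "olfactory_L": [[2, -12], [2, -1], [13, -1], [13, -12]],
    "olfactory_R": [[2, 1], [2, 12], [13, 12], [13, 1]],
    "frontal_L": [[16, -14], [16, -1], [30, -1], [30, -14]],
    "frontal_R": [[16, 1], [16, 14], [30, 14], [30, 1]],
    "cingulate_L": [[31, -6], [31, -1], [45, -1], [45, -6]],
    "cingulate_R": [[31, 1], [31, 6], [45, 6], [45, 1]],
    "motor_L": [[31, -23], [31, -8], [45, -8], [45, -23]],
    "motor_R": [[31, 8], [31, 23], [45, 23], [45, 8]],
    "somatosensory_L": [[47, -28], [47, -2], [62, -2], [62, -28]],
    "somatosensory_R": [[47, 2], [47, 28], [62, 28], [62, 2]],
    "auditory_L": [[47, -38], [47, -30], [62, -30], [62, -38]],
    "auditory_R": [[47, 30], [47, 38], [62, 38], [62, 30]],
    "parietal_L": [[64, -20], [64, -5], [70, -5], [70, -20]],
    "parietal_R": [[64, 5], [64, 20], [70, 20], [70, 5]],
    "retrosplenial_L": [[64, -4], [64, -1], [82, -1], [82, -4]],
    "retrosplenial_R": [[64, 1], [64, 4], [82, 4], [82, 1]],
    "visual_L": [[72, -25], [72, -6], [82, -6], [82, -25]],
    "visual_R": [[72, 6], [72, 25], [82, 25], [82, 6]],
    "superior_colliculus_L": [[86, -10], [86, -1], [95, -1], [95, -10]],
    "superior_colliculus_R": [[86, 1], [86, 10], [95, 10], [95, 1]]
  }
}
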