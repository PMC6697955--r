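Sigmoidoscopy is the minimally invasive medical examination of the colon, specifically the sigmoid colon, the distal portion of the large intestine closest to the rectum. Flexible sigmoidoscopy uses a flexible endoscope to inspect the lining of the sigmoid colon and is a common screening test for polyps and cancers of the large bowel.
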