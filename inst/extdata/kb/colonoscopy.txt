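Colonoscopy is the endoscopic examination of the colon along its whole length, together with the distal part of the small intestine. A flexible camera is passed through the rectum and advanced around the entire large intestine. It can detect ulceration and polyps of the large bowel and is used for screening and biopsy.
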