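<svg xmlns="http://www.w3.org/2000/svg" width="600" height="120" viewBox="0 0 600 120">
<rect x="40.0" y="60" width="520.0" height="14" fill="#dddddd" stroke="#333333"/>
<rect class="dbd" x="110.3" y="60" width="379.5" height="14" fill="#2b6cb0" stroke="#333333"/>
<text x="40.0" y="94" font-size="12" font-family="sans-serif">golden (75 aa)</text>
</svg>
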