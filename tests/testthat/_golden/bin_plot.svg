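<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" width="480" height="480" viewBox="0 0 480 480">
<rect x="0.00" y="0.00" width="480.00" height="480.00" fill="white" stroke="none"/>
<rect x="50.00" y="395.45" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="50.00" y="291.82" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="50.00" y="222.73" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="50.00" y="188.18" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="97.50" y="360.91" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="97.50" y="326.36" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="97.50" y="291.82" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="97.50" y="257.27" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="97.50" y="222.73" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="97.50" y="188.18" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="97.50" y="153.64" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="97.50" y="119.09" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="97.50" y="50.00" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="145.00" y="395.45" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="145.00" y="360.91" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="145.00" y="326.36" width="47.50" height="34.55" fill="#3a50c6" stroke="none"/>
<rect x="145.00" y="291.82" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="145.00" y="257.27" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="145.00" y="222.73" width="47.50" height="34.55" fill="#3248cd" stroke="none"/>
<rect x="145.00" y="188.18" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="145.00" y="153.64" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="145.00" y="119.09" width="47.50" height="34.55" fill="#d73c28" stroke="none"/>
<rect x="145.00" y="84.55" width="47.50" height="34.55" fill="#d73c28" stroke="none"/>
<rect x="145.00" y="50.00" width="47.50" height="34.55" fill="#d73c28" stroke="none"/>
<rect x="192.50" y="360.91" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="192.50" y="326.36" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="192.50" y="291.82" width="47.50" height="34.55" fill="#3f57c0" stroke="none"/>
<rect x="192.50" y="257.27" width="47.50" height="34.55" fill="#2d42d2" stroke="none"/>
<rect x="192.50" y="222.73" width="47.50" height="34.55" fill="#384ec7" stroke="none"/>
<rect x="192.50" y="188.18" width="47.50" height="34.55" fill="#4b64b4" stroke="none"/>
<rect x="192.50" y="153.64" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="240.00" y="395.45" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="240.00" y="360.91" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="240.00" y="326.36" width="47.50" height="34.55" fill="#3e55c1" stroke="none"/>
<rect x="240.00" y="291.82" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="240.00" y="257.27" width="47.50" height="34.55" fill="#3046cf" stroke="none"/>
<rect x="240.00" y="222.73" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="240.00" y="188.18" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="287.50" y="326.36" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="287.50" y="291.82" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="287.50" y="257.27" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="287.50" y="222.73" width="47.50" height="34.55" fill="#283cd7" stroke="none"/>
<rect x="287.50" y="188.18" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="287.50" y="153.64" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="335.00" y="257.27" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="335.00" y="222.73" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="335.00" y="188.18" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="382.50" y="326.36" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<rect x="382.50" y="291.82" width="47.50" height="34.55" fill="#bbbbbb" stroke="none"/>
<line x1="335.00" y1="50.00" x2="335.00" y2="430.00" stroke="black" stroke-width="1"/>
<line x1="50.00" y1="188.18" x2="430.00" y2="188.18" stroke="black" stroke-width="1"/>
<text x="54.00" y="66.00" fill="black" font-size="12" font-family="sans-serif" text-anchor="start">10.91</text>
<text x="426.00" y="66.00" fill="black" font-size="12" font-family="sans-serif" text-anchor="end">0.00</text>
<text x="54.00" y="424.00" fill="black" font-size="12" font-family="sans-serif" text-anchor="start">86.97</text>
<text x="426.00" y="424.00" fill="black" font-size="12" font-family="sans-serif" text-anchor="end">2.12</text>
<text x="54.00" y="82.00" fill="red" font-size="12" font-family="sans-serif" text-anchor="start">86.11%</text>
<rect x="50.00" y="444.00" width="60.00" height="10.00" fill="#283cd7" stroke="none"/>
<rect x="110.00" y="444.00" width="60.00" height="10.00" fill="#d73c28" stroke="none"/>
<text x="176.00" y="453.00" fill="black" font-size="10" font-family="sans-serif" text-anchor="start">FREQ: min 0.0000 / max 100.0000</text>
<text x="240.00" y="472.00" fill="black" font-size="11" font-family="sans-serif" text-anchor="middle">SSC</text>
<text x="12.00" y="240.00" fill="black" font-size="11" font-family="sans-serif" text-anchor="middle">FCER1A</text>
</svg>
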