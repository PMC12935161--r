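<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" width="2460.00" height="165.00" viewBox="-180.00 0 2460.00 165.00">
<text x="-10.00" y="34.00" font-family="monospace" font-size="11" text-anchor="end" fill="#222222">TOYT01</text>
<rect x="0.00" y="25.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<rect x="300.00" y="25.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<line x1="200.00" y1="30.00" x2="300.00" y2="30.00" stroke="#666666" stroke-width="1.5"/>
<rect x="600.00" y="25.50" width="250.00" height="9.00" fill="#7ea6c9"/>
<line x1="500.00" y1="30.00" x2="600.00" y2="30.00" stroke="#666666" stroke-width="1.5"/>
<rect x="1250.00" y="25.50" width="250.00" height="9.00" fill="#7ea6c9"/>
<line x1="850.00" y1="30.00" x2="1250.00" y2="30.00" stroke="#666666" stroke-width="1.5"/>
<rect x="1600.00" y="25.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<line x1="1500.00" y1="30.00" x2="1600.00" y2="30.00" stroke="#666666" stroke-width="1.5"/>
<rect x="100.00" y="19.50" width="100.00" height="21.00" fill="#2b5d8c"/>
<rect x="300.00" y="19.50" width="200.00" height="21.00" fill="#2b5d8c"/>
<rect x="600.00" y="19.50" width="250.00" height="21.00" fill="#2b5d8c"/>
<rect x="1250.00" y="19.50" width="250.00" height="21.00" fill="#2b5d8c"/>
<rect x="1600.00" y="19.50" width="52.00" height="21.00" fill="#2b5d8c"/>
<text x="-10.00" y="64.00" font-family="monospace" font-size="11" text-anchor="end" fill="#222222">TOYT02</text>
<rect x="0.00" y="55.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<rect x="300.00" y="55.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<line x1="200.00" y1="60.00" x2="300.00" y2="60.00" stroke="#666666" stroke-width="1.5"/>
<rect x="1250.00" y="55.50" width="250.00" height="9.00" fill="#7ea6c9"/>
<line x1="500.00" y1="60.00" x2="1250.00" y2="60.00" stroke="#666666" stroke-width="1.5"/>
<rect x="1600.00" y="55.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<line x1="1500.00" y1="60.00" x2="1600.00" y2="60.00" stroke="#666666" stroke-width="1.5"/>
<rect x="100.00" y="49.50" width="100.00" height="21.00" fill="#2b5d8c"/>
<rect x="300.00" y="49.50" width="200.00" height="21.00" fill="#2b5d8c"/>
<rect x="1250.00" y="49.50" width="250.00" height="21.00" fill="#2b5d8c"/>
<rect x="1600.00" y="49.50" width="53.00" height="21.00" fill="#2b5d8c"/>
<text x="-10.00" y="94.00" font-family="monospace" font-size="11" text-anchor="end" fill="#222222">TOYT03</text>
<rect x="400.00" y="85.50" width="100.00" height="9.00" fill="#7ea6c9"/>
<rect x="600.00" y="85.50" width="250.00" height="9.00" fill="#7ea6c9"/>
<line x1="500.00" y1="90.00" x2="600.00" y2="90.00" stroke="#666666" stroke-width="1.5"/>
<rect x="1250.00" y="85.50" width="250.00" height="9.00" fill="#7ea6c9"/>
<line x1="850.00" y1="90.00" x2="1250.00" y2="90.00" stroke="#666666" stroke-width="1.5"/>
<rect x="1600.00" y="85.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<line x1="1500.00" y1="90.00" x2="1600.00" y2="90.00" stroke="#666666" stroke-width="1.5"/>
<rect x="600.00" y="79.50" width="250.00" height="21.00" fill="#2b5d8c"/>
<rect x="1250.00" y="79.50" width="250.00" height="21.00" fill="#2b5d8c"/>
<rect x="1600.00" y="79.50" width="40.00" height="21.00" fill="#2b5d8c"/>
<text x="-10.00" y="124.00" font-family="monospace" font-size="11" text-anchor="end" fill="#222222">TOYT04</text>
<rect x="0.00" y="115.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<rect x="300.00" y="115.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<line x1="200.00" y1="120.00" x2="300.00" y2="120.00" stroke="#666666" stroke-width="1.5"/>
<rect x="600.00" y="115.50" width="250.00" height="9.00" fill="#7ea6c9"/>
<line x1="500.00" y1="120.00" x2="600.00" y2="120.00" stroke="#666666" stroke-width="1.5"/>
<rect x="950.00" y="115.50" width="200.00" height="9.00" fill="#7ea6c9"/>
<line x1="850.00" y1="120.00" x2="950.00" y2="120.00" stroke="#666666" stroke-width="1.5"/>
<rect x="100.00" y="109.50" width="100.00" height="21.00" fill="#2b5d8c"/>
<rect x="300.00" y="109.50" width="200.00" height="21.00" fill="#2b5d8c"/>
<rect x="600.00" y="109.50" width="201.00" height="21.00" fill="#2b5d8c"/>
<line x1="0.00" y1="15.00" x2="0.00" y2="135.00" stroke="#c0392b" stroke-width="1.5"/>
<line x1="400.00" y1="15.00" x2="400.00" y2="135.00" stroke="#c0392b" stroke-width="1.5"/>
<line x1="2008.92" y1="23.00" x2="2009.83" y2="23.00" stroke="#8da0cb" stroke-width="1.5"/>
<rect x="2009.09" y="18.00" width="0.42" height="10.00" fill="#8da0cb"/>
<line x1="2009.24" y1="18.00" x2="2009.24" y2="28.00" stroke="#222222" stroke-width="1.5"/>
<line x1="1840.46" y1="37.00" x2="1844.22" y2="37.00" stroke="#fc8d62" stroke-width="1.5"/>
<rect x="1840.79" y="32.00" width="1.96" height="10.00" fill="#fc8d62"/>
<line x1="1841.62" y1="32.00" x2="1841.62" y2="42.00" stroke="#222222" stroke-width="1.5"/>
<text x="2050.00" y="34.00" font-family="monospace" font-size="11" text-anchor="start" fill="#222222">q=3.1e-173 log2FC=-2.00 *</text>
<line x1="1973.69" y1="53.00" x2="1974.91" y2="53.00" stroke="#8da0cb" stroke-width="1.5"/>
<rect x="1973.92" y="48.00" width="0.56" height="10.00" fill="#8da0cb"/>
<line x1="1974.12" y1="48.00" x2="1974.12" y2="58.00" stroke="#222222" stroke-width="1.5"/>
<line x1="1973.84" y1="67.00" x2="1975.13" y2="67.00" stroke="#fc8d62" stroke-width="1.5"/>
<rect x="1973.96" y="62.00" width="0.67" height="10.00" fill="#fc8d62"/>
<line x1="1974.24" y1="62.00" x2="1974.24" y2="72.00" stroke="#222222" stroke-width="1.5"/>
<text x="2050.00" y="64.00" font-family="monospace" font-size="11" text-anchor="start" fill="#222222">q=1 log2FC=+0.00</text>
<line x1="1924.16" y1="83.00" x2="1925.97" y2="83.00" stroke="#8da0cb" stroke-width="1.5"/>
<rect x="1924.50" y="78.00" width="0.84" height="10.00" fill="#8da0cb"/>
<line x1="1924.80" y1="78.00" x2="1924.80" y2="88.00" stroke="#222222" stroke-width="1.5"/>
<line x1="1924.39" y1="97.00" x2="1926.31" y2="97.00" stroke="#fc8d62" stroke-width="1.5"/>
<rect x="1924.56" y="92.00" width="1.00" height="10.00" fill="#fc8d62"/>
<line x1="1924.98" y1="92.00" x2="1924.98" y2="102.00" stroke="#222222" stroke-width="1.5"/>
<text x="2050.00" y="94.00" font-family="monospace" font-size="11" text-anchor="start" fill="#222222">q=1 log2FC=+0.00</text>
<line x1="1840.00" y1="113.00" x2="1843.57" y2="113.00" stroke="#8da0cb" stroke-width="1.5"/>
<rect x="1840.69" y="108.00" width="1.66" height="10.00" fill="#8da0cb"/>
<line x1="1841.27" y1="108.00" x2="1841.27" y2="118.00" stroke="#222222" stroke-width="1.5"/>
<line x1="2009.03" y1="127.00" x2="2010.00" y2="127.00" stroke="#fc8d62" stroke-width="1.5"/>
<rect x="2009.12" y="122.00" width="0.50" height="10.00" fill="#fc8d62"/>
<line x1="2009.33" y1="122.00" x2="2009.33" y2="132.00" stroke="#222222" stroke-width="1.5"/>
<text x="2050.00" y="124.00" font-family="monospace" font-size="11" text-anchor="start" fill="#222222">q=3.1e-173 log2FC=+2.00 *</text>
<text x="1840.00" y="154.00" font-family="monospace" font-size="11" text-anchor="start" fill="#222222">log2 CPM</text>
</svg>
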