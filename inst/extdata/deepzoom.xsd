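<?xml version="1.0" encoding="UTF-8"?>
<!-- Deep Zoom Image descriptor schema (deepzoom 2008 namespace, single-image
     subset: Image element with TileSize/Overlap/Format and a Size child). -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="http://schemas.microsoft.com/deepzoom/2008"
           xmlns:dz="http://schemas.microsoft.com/deepzoom/2008"
           elementFormDefault="qualified">
  <xs:element name="Image">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="Size">
          <xs:complexType>
            <xs:attribute name="Width" type="xs:positiveInteger" use="required"/>
            <xs:attribute name="Height" type="xs:positiveInteger" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="TileSize" type="xs:positiveInteger" use="required"/>
      <xs:attribute name="Overlap" type="xs:nonNegativeInteger" use="required"/>
      <xs:attribute name="Format" use="required">
        <xs:simpleType>
          <xs:restriction base="xs:string">
            <xs:enumeration value="png"/>
            <xs:enumeration value="jpeg"/>
            <xs:enumeration value="jpg"/>
          </xs:restriction>
        </xs:simpleType>
      </xs:attribute>
    </xs:complexType>
  </xs:element>
</xs:schema>
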